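# Demonstration pipeline configuration: synthetic development suite
# (four cohorts, logistic outcome model with between-study heterogeneity)
# plus a synthetic validation register.
simulate:
  outcome_model: logistic
  study_intercept_sd: 0.3
n_bootstrap: 100
thresholds:
  lo: 0.005
  hi: 0.30
  step: 0.005
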