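Package: ulcerscore
Title: Development and Validation of an Integer Clinical Prediction Rule
    for Diabetic Foot Ulceration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for developing, validating, and appraising a simple
    integer clinical prediction rule (CPR) for the two-year risk of diabetic
    foot ulceration from three bedside predictors: monofilament
    insensitivity, absent pedal pulses, and history of ulcer or amputation.
    Covers harmonization of multi-cohort individual participant data,
    pooled logistic prognostic modelling with bootstrap shrinkage checks,
    conversion of coefficients to integer score weights, population-average
    (marginal) per-score risk estimation over study-level random intercepts,
    external validation (C-statistic with DeLong confidence interval,
    calibration slope and calibration-in-the-large, grouped calibration),
    and decision-curve net-benefit analysis with a referral-threshold
    recommendation. A synthetic multi-study cohort generator reproduces the
    statistical structure of the development and validation cohorts so the
    whole pipeline is testable without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    lme4,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
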