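---
title: "Methods: developing and validating an integer foot-ulcer risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developing and validating an integer foot-ulcer risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulcerscore)
```

## The problem and the rule

People with diabetes are at substantial risk of foot ulceration, the main
precursor of lower-limb amputation. Screening in routine care asks for a
tool that is simple enough to apply at the bedside and still quantifies
risk well enough to steer referral to preventative foot care. `ulcerscore`
implements the full life cycle of such a tool: an integer clinical
prediction rule (CPR) built from three binary findings —

* insensitivity to a 10 g monofilament anywhere on the foot (peripheral
  neuropathy),
* any absent pedal pulse of the four (dorsalis pedis and posterior tibial,
  each foot; peripheral arterial disease),
* history of previous ulcer or amputation —

predicting ulceration within 2 years. The rule awards 1 point each for the
first two findings and 2 points for positive history, giving scores 0–4
that map to a published table of population-average risks.

## Data model and harmonization

Individual-participant data (IPD) arrive as one row per person with a
study label, the three predictors, and the binary 2-year outcome.
Predictors may arrive pre-coded or raw (per-site monofilament results,
four pulse examinations); `read_cohort_csv()` supports both dialects.
Coding follows three-valued logic:

* monofilament: 1 if insensate at any site; 0 if felt at all non-missing
  sites (permissive default — insensitivity *anywhere* is what the rule
  keys on; `strict = TRUE` instead withholds a 0 unless every site was
  observed);
* pulses: 1 if any of the four is absent; 0 only if all four are present,
  so a single unexamined pulse leaves the coding missing;
* history: the OR of prior ulcer and prior amputation, with missing
  propagation (a missing component can conceal a 1).

Analysis is complete-case only (`complete_case_filter()`); the cohorts the
generator emulates had 97–98% complete data, which is why no imputation
machinery exists anywhere in the package. A known imperfection left
deliberately unadjusted: a healthy minority congenitally lack the dorsalis
pedis pulse, which the coding treats like any other absent pulse.

## The prognostic model and its conversion to a score

The prognostic model is pooled logistic regression of the outcome on the
three predictors, all forced into the model irrespective of significance
(`fit_logistic()`, IRLS with relative-deviance tolerance 1e-10, at most
100 iterations; non-convergence and separation are errors, never silent
results). Wald 95% intervals are used throughout, on the log-odds scale
and exponentiated for odds ratios; profile likelihood is not implemented,
as symmetric Wald intervals are what per-score risk propagation needs.

Adequacy of the sample size is checked with a bootstrap uniform shrinkage
factor (`shrinkage_factor()`, default 500 seeded resamples): each resample
refits the model and the calibration slope of that refit's linear
predictor on the original data is recorded; the mean slope is the
shrinkage factor, with the heuristic (model chi-squared − df)/chi-squared
as a cross-check. Resamples that fail to refit are dropped (an error above
20%). Values near 1 mean negligible optimism; in small, overfitted
configurations the factor falls well below 0.9.

Conversion to the integer rule rounds each raw coefficient to the nearest
integer, ties away from zero (`convert_to_cpr()`). With coefficients near
(1.11, 0.70, 1.95) this yields weights (1, 1, 2). Scaling by a reference
coefficient before rounding (the other common convention) gives the same
weights here and is intentionally not a second code path; a weight that
rounds to zero triggers a warning since that predictor then carries no
information into the score.

## Population-average risks per score

The modelling procedure is repeated with the score as the only predictor
(`fit_score_model()`). With several studies this is a random-intercept
logistic model — study-level intercepts normal with SD $\sigma_u$ —
fitted by adaptive Gauss–Hermite quadrature (`lme4::glmer`, 10 points by
default); with one study it reduces to ordinary logistic regression with
$\sigma_u = 0$.

The fitted intercept and slope are *cluster-specific*. Risk communicated
to a patient drawn from the population of settings should average over
between-study variation:
$$p_k = \int \operatorname{logit}^{-1}(\alpha + \gamma k + u)\,
  \varphi(u; \sigma_u)\, du,$$
evaluated by Gauss–Hermite quadrature with 40 nodes
(`population_average_risk()`; the integral is smooth, and 40 nodes agree
with a $10^6$-draw Monte Carlo average to better than 5e-4). Confidence
intervals marginalize the Wald endpoints of $\alpha + \gamma k$ the same
way. An analytic alternative divides the linear predictor by
$\sqrt{1 + 0.346\,\sigma_u^2}$; against quadrature it is accurate to
0.005 absolute probability for $\sigma_u \le 0.6$ and to 0.007 at
$\sigma_u = 1$ (worst near risks of 0.3), so quadrature is the default and
the approximation exists for transparency only. Marginal risks are pulled
toward one half relative to conditional risks at the same linear
predictor — the familiar attenuation of population-average effects.

One genuinely open design point: whether the prognostic model itself
should carry study-level random intercepts. The package fits the pooled
model by default — the development estimates it reproduces come from a
single pooled fit — and reserves the random-intercept machinery for the
score model, where the risk table's population-average framing requires
it. `fit_score_model()` accepts any study structure, so the other choice
is a one-line variation.

## External validation

`validate_cpr()` reports, on a new dataset:

* **Discrimination**: the C-statistic in its rank (Mann–Whitney) form,
  exact over all event × non-event pairs with ties counted one half, with
  a DeLong placement-based interval — chosen over the bootstrap for
  determinism. `roc_points()` returns one point per threshold between
  observed scores plus the (0,0) and (1,1) anchors; its trapezoidal area
  equals the tie-corrected C-statistic to 1e-12, an identity the tests
  enforce on random instances.
* **Calibration**: the calibration slope (coefficient of the linear
  predictor in a logistic refit; 1 is ideal) and calibration-in-the-large
  (intercept of a refit with the linear predictor as offset; 0 is ideal).
  Calibration is defined on the log-odds scale, so raw integer scores are
  refused: the score model supplies the linear predictor
  $\alpha + \gamma \cdot \text{score}$.
* **Grouped calibration**: per observed score, the event proportion with
  an exact Clopper–Pearson interval against the table's predicted risk —
  exact intervals because high-score groups are small (a few hundred or
  fewer participants).

## Net benefit and the referral threshold

Decision-curve analysis scores a strategy at threshold probability $p_t$
by $NB = TP/n - FP/n \cdot p_t/(1-p_t)$, comparing risk-guided treatment
(treat when predicted risk $\ge p_t$; the closed bound ensures a cut
placed exactly at a table risk treats that score group) against treat-all
and treat-none. The default grid is 0.005–0.30 in steps of 0.005,
spanning the actionable low end of 2-year risks.

The referral recommendation exploits the discreteness of the rule: for
$p_t$ between the table risks of scores $k-1$ and $k$, the risk-guided
strategy treats exactly those scoring $k$ or more, so each score owns an
interval of the curve. `recommend_threshold()` returns the smallest score
whose interval (clipped to a clinically relevant range, default 0.02–0.15
— referral thresholds for preventative foot care plausibly sit between
"2% is too low to act on" and "15% would miss most preventable ulcers")
is never worse than either reference and strictly beats treat-all
somewhere. Requiring a strict win excludes the degenerate treat-everyone
cut at score 0, and a flat risk table returns an explicit
no-recommendation result rather than an error. The exact grid and
dominance rule behind the original "6% or more" advice are not public;
this reconstruction reproduces it on registers simulated from the
published table. No harm/cost weighting is applied beyond the odds
weighting intrinsic to net benefit.

## What the synthetic generator does and does not emulate

`simulate_cohort()` and the built-in development/validation specifications
reproduce the multi-study *structure* the analysis assumes: per-study
sizes (complete-data 6478, 1175, 360, 242; validation 3324), marginal
predictor prevalences, per-study outcome rates (pooled 5.2% in
development), and — in the logistic outcome form — a three-predictor risk
model with a study-level intercept offset drawn once per cohort.
Choices a scientist must make where published information runs out:

* **Predictor dependence.** Only marginal prevalences are published, so
  predictors are independent by default; a shared-latent-Gaussian hook
  (`predictor_correlation`) exists because neuropathy, arteriopathy and
  ulcer history are positively associated in practice, but no published
  joint distribution exists to calibrate it.
* **Between-study heterogeneity.** The intercept SD behind the published
  population-average table is not reported; the suite default of 0.3 on
  the log-odds scale is a stand-in giving moderate heterogeneity (about a
  1.8-fold odds range across typical studies), chosen once and not tuned.
* **History composition.** Among participants with positive history, 80%
  are assigned prior ulceration (some with amputation); only the combined
  history enters any model, so this split is cosmetic.
* **Missingness** is MCAR, applied per field at a configurable rate to
  four field groups (monofilament, pulses, outcome, and the history pair
  jointly, so the derived history behaves as one field — making
  complete-case retention exactly $(1-m)^4$ in expectation). The emulated
  cohorts reported 97–98% complete data with no imputation.

Not emulated: outcome-linked demographic covariates (age, sex, diabetes
duration enter no model), time-to-ulceration or competing risk of death
(inputs must already be 2-year binaries), informative missingness, and
site-level congenital pulse absence. Passing tests on these synthetic
cohorts therefore demonstrate statistical correctness of the machinery
under the stated generating model — not clinical transportability, which
only new external data can show.

## Numerical and testing conventions

Randomness always flows through explicit seeds (specs carry seeds;
multi-stage runs derive per-stage seeds from one root recorded in the run
manifest), and identical inputs reproduce byte-identical artifacts. The
test suite sizes its simulations for tightness per unit time: exhaustive
truth tables for the coders; closed-form 2×2 checks and 200-replicate
Wald-coverage experiments at the development scale (n = 8255) for the
fits; 20,000-row registers for self-validation; brute-force pair counting
and confusion-matrix oracles on ~1000 random small instances for the
C-statistic and net benefit; and shrinkage evaluated at n = 200, 2000,
and 20,000 to watch optimism vanish with sample size.

## Limitations

The package validates a rule against data; it does not recalibrate or
update one (no intercept re-estimation for new settings), select
variables, or fit penalized models. The bootstrap definition of the
shrinkage factor is a standard choice rather than a verbatim reproduction
of the original supplementary procedure. Real-data idiosyncrasies —
correlated predictors, drifting case mix, non-random missingness — are
outside what the generator can certify.
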