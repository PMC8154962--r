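#' Simulate one synthetic cohort of participant records
#'
#' Generates individual-participant records with the statistical structure
#' assumed by the downstream modelling: three binary bedside predictors drawn
#' with the specified marginal prevalences (optionally correlated through a
#' shared latent Gaussian), a binary 2-year ulcer outcome drawn either at a
#' fixed marginal rate or from a logistic risk model with a study-level
#' random intercept, and completely-at-random missingness.
#'
#' The study-level intercept offset is drawn once per cohort (between-study
#' heterogeneity), not per participant. History of ulcer/amputation is
#' generated as a single binary at `prev_hist` and then split into
#' `prior_ulcer` / `prior_amputation` components (most history is prior
#' ulceration); missingness strikes the two components jointly so that the
#' derived history behaves as one field.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`. Identical
#'   spec and seed produce identical records.
#' @return A data frame with one row per participant and columns
#'   `study_label`, `mono_insensate`, `pulses_absent`, `prior_ulcer`,
#'   `prior_amputation`, `ulcer_2yr` (0/1 integers, `NA` for missing).
#' @export
#' @examples
#' spec <- cohort_spec("demo", n = 500, prev_mono = 0.2, prev_pulse = 0.3,
#'                     prev_hist = 0.05, marginal_rate = 0.05, seed = 42)
#' head(simulate_cohort(spec))
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    rho <- spec$predictor_correlation
    # latent equicorrelated Gaussian; thresholds give the marginal prevalences
    z <- matrix(stats::rnorm(3L * n), nrow = n)
    if (rho > 0) {
      shared <- stats::rnorm(n)
      z <- sqrt(rho) * shared + sqrt(1 - rho) * z
    }
    mono  <- as.integer(z[, 1] < stats::qnorm(spec$prev_mono))
    pulse <- as.integer(z[, 2] < stats::qnorm(spec$prev_pulse))
    hist  <- as.integer(z[, 3] < stats::qnorm(spec$prev_hist))

    # split history into components: mostly prior ulcer, some amputation
    u_split <- stats::runif(n)
    prior_ulcer <- ifelse(hist == 1L, as.integer(u_split < 0.8), 0L)
    u_amp <- stats::runif(n)
    prior_amp <- ifelse(hist == 1L,
                        ifelse(prior_ulcer == 1L, as.integer(u_amp < 0.25), 1L),
                        0L)

    om <- spec$outcome_model
    if (om$type == "marginal_rate") {
      p <- rep(om$rate, n)
    } else {
      offset <- if (spec$study_intercept_sd > 0) {
        stats::rnorm(1L, sd = spec$study_intercept_sd)
      } else 0
      eta <- om$intercept + offset +
        om$coefficients[1] * mono +
        om$coefficients[2] * pulse +
        om$coefficients[3] * hist
      p <- inv_logit(eta)
    }
    ulcer <- as.integer(stats::runif(n) < p)

    df <- data.frame(study_label = rep(spec$study_label, n),
                     mono_insensate = mono,
                     pulses_absent = pulse,
                     prior_ulcer = prior_ulcer,
                     prior_amputation = prior_amp,
                     ulcer_2yr = ulcer,
                     stringsAsFactors = FALSE)

    if (spec$missing_rate > 0) {
      m <- spec$missing_rate
      df$mono_insensate[stats::runif(n) < m] <- NA_integer_
      df$pulses_absent[stats::runif(n) < m] <- NA_integer_
      hit <- stats::runif(n) < m  # history pair struck jointly
      df$prior_ulcer[hit] <- NA_integer_
      df$prior_amputation[hit] <- NA_integer_
      df$ulcer_2yr[stats::runif(n) < m] <- NA_integer_
    }
    df
  })
}

# Development-study parameters: complete-data sizes with per-study predictor
# prevalences and 2-year ulcer rates. Two large community cohorts, two
# smaller secondary-care cohorts with markedly higher baseline risk.
dev_params <- data.frame(
  study_label = c("dev_community_1", "dev_community_2",
                  "dev_secondary_1", "dev_secondary_2"),
  n = c(6478L, 1175L, 360L, 242L),
  prev_mono = c(0.194, 0.223, 0.461, 0.746),
  prev_pulse = c(0.296, 0.188, 0.203, 0.145),
  prev_hist = c(0.047, 0.072, 0.381, 0.714),
  rate = c(0.044, 0.019, 0.144, 0.278),
  stringsAsFactors = FALSE
)

val_params <- data.frame(
  study_label = "validation",
  n = 3324L,
  prev_mono = 0.207,
  prev_pulse = 0.140,
  prev_hist = 0.057,
  rate = 0.039,
  stringsAsFactors = FALSE
)

#' Cohort specifications for the synthetic development suite
#'
#' Returns the four development-study [cohort_spec()]s (complete-data sizes
#' 6478, 1175, 360 and 242; pooled 8255) with their published predictor
#' prevalences and 2-year ulcer rates. The outcome may be generated either
#' at each study's marginal rate (the default, which reproduces the pooled
#' 5.2% event rate) or from the three-predictor logistic risk model with a
#' study-level random intercept (useful for parameter-recovery work).
#'
#' @param outcome_model `"marginal_rate"` or `"logistic"`.
#' @param intercept,coefficients Logistic outcome parameters (log-odds),
#'   used when `outcome_model = "logistic"`. Defaults: intercept
#'   `logit(0.022)` and coefficients 1.11 (monofilament), 0.70 (pulses),
#'   1.95 (history).
#' @param study_intercept_sd Between-study intercept SD for the logistic
#'   form; default 0.3 on the log-odds scale (a stand-in value: the
#'   between-study variance behind the published population-average risks is
#'   not reported).
#' @param missing_rate Per-field MCAR missingness rate.
#' @return A list of four `cohort_spec` objects.
#' @export
development_cohort_specs <- function(outcome_model = c("marginal_rate", "logistic"),
                                     intercept = logit(0.022),
                                     coefficients = c(1.11, 0.70, 1.95),
                                     study_intercept_sd = 0.3,
                                     missing_rate = 0) {
  outcome_model <- match.arg(outcome_model)
  lapply(seq_len(nrow(dev_params)), function(i) {
    p <- dev_params[i, ]
    if (outcome_model == "marginal_rate") {
      cohort_spec(p$study_label, p$n, p$prev_mono, p$prev_pulse, p$prev_hist,
                  marginal_rate = p$rate, missing_rate = missing_rate)
    } else {
      cohort_spec(p$study_label, p$n, p$prev_mono, p$prev_pulse, p$prev_hist,
                  intercept = intercept, coefficients = coefficients,
                  study_intercept_sd = study_intercept_sd,
                  missing_rate = missing_rate)
    }
  })
}

#' Cohort specification for the synthetic validation register
#'
#' The external validation study: 3324 participants with complete data,
#' predictor prevalences 20.7% / 14.0% / 5.7% and a 3.9% 2-year ulcer rate.
#'
#' @inheritParams development_cohort_specs
#' @return A single `cohort_spec`.
#' @export
validation_cohort_spec <- function(outcome_model = c("marginal_rate", "logistic"),
                                   intercept = logit(0.022),
                                   coefficients = c(1.11, 0.70, 1.95),
                                   study_intercept_sd = 0,
                                   missing_rate = 0) {
  outcome_model <- match.arg(outcome_model)
  p <- val_params
  if (outcome_model == "marginal_rate") {
    cohort_spec(p$study_label, p$n, p$prev_mono, p$prev_pulse, p$prev_hist,
                marginal_rate = p$rate, missing_rate = missing_rate)
  } else {
    cohort_spec(p$study_label, p$n, p$prev_mono, p$prev_pulse, p$prev_hist,
                intercept = intercept, coefficients = coefficients,
                study_intercept_sd = study_intercept_sd,
                missing_rate = missing_rate)
  }
}

#' Simulate the four-study development suite
#'
#' Generates all four development cohorts and returns them pooled in one
#' data frame (8255 rows with `missing_rate = 0`). Per-cohort seeds are
#' derived deterministically from the root seed.
#'
#' @param seed Integer root seed.
#' @param ... Passed to [development_cohort_specs()].
#' @return A data frame of participant records across the four studies.
#' @export
#' @examples
#' suite <- simulate_development_suite(seed = 1)
#' nrow(suite)            # 8255
#' mean(suite$ulcer_2yr)  # close to 0.052
simulate_development_suite <- function(seed, ...) {
  specs <- development_cohort_specs(...)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(specs)))
  do.call(rbind, Map(function(s, sd) simulate_cohort(s, seed = sd),
                     specs, sub_seeds))
}

#' Simulate a register of participants from a fitted score model
#'
#' Draws integer CPR scores from a given score distribution and binary
#' outcomes from the score logistic model; used for self-validation
#' exercises (calibration of a model against data generated from itself).
#'
#' @param n Number of participants.
#' @param alpha Score-model intercept (log-odds at score 0).
#' @param gamma Per-point log-odds ratio.
#' @param score_probs Probabilities over scores `0:(length(score_probs)-1)`;
#'   the default is the development-data score mix (4646, 2406, 676, 358,
#'   169 participants at scores 0-4).
#' @param seed Integer seed.
#' @return A data frame with columns `score`, `ulcer_2yr`, and the
#'   model's linear predictor `lp = alpha + gamma * score`.
#' @export
#' @examples
#' reg <- simulate_score_register(2000, alpha = logit(0.024),
#'                                gamma = log(2.57), seed = 7)
#' table(reg$score)
simulate_score_register <- function(n, alpha, gamma,
                                    score_probs = c(4646, 2406, 676, 358, 169) / 8255,
                                    seed = NULL) {
  stopifnot(n >= 1, all(score_probs >= 0), sum(score_probs) > 0)
  score_probs <- score_probs / sum(score_probs)
  with_seed(seed, {
    score <- sample(seq_along(score_probs) - 1L, n, replace = TRUE,
                    prob = score_probs)
    lp <- alpha + gamma * score
    data.frame(score = score,
               ulcer_2yr = as.integer(stats::runif(n) < inv_logit(lp)),
               lp = lp)
  })
}

#' Write participant records to CSV
#'
#' Writes the standard cohort layout (`study_label`, `mono_insensate`,
#' `pulses_absent`, `prior_ulcer`, `prior_amputation`, `ulcer_2yr`) with
#' missing values as empty fields.
#'
#' @param records Data frame of participant records.
#' @param path Output file path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
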