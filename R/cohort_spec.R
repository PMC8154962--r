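#' Specify the generative parameters of one synthetic cohort
#'
#' A `cohort_spec` describes one study in a multi-study individual-participant
#' dataset: its size, the marginal prevalence of each of the three bedside
#' predictors, the outcome-generating model, between-study baseline-risk
#' heterogeneity, and a per-field missingness rate. It is consumed by
#' [simulate_cohort()].
#'
#' The outcome model takes one of two forms:
#' \describe{
#'   \item{marginal rate}{`marginal_rate` gives the overall 2-year ulcer
#'     probability, applied to every participant irrespective of predictors.
#'     This reproduces a study's published outcome rate exactly in
#'     expectation.}
#'   \item{logistic}{`intercept` and `coefficients` (length 3, ordered
#'     monofilament, pulses, history) define a logistic risk model on the
#'     log-odds scale; a study-level intercept offset drawn once per cohort
#'     from N(0, `study_intercept_sd`^2) induces between-study heterogeneity.}
#' }
#'
#' @param study_label Character study identifier.
#' @param n Positive integer number of participants.
#' @param prev_mono,prev_pulse,prev_hist Marginal prevalences in \[0, 1\] of
#'   monofilament insensitivity, any absent pedal pulse, and history of
#'   ulcer/amputation.
#' @param marginal_rate Overall outcome probability in \[0, 1\], or `NULL`
#'   when a logistic outcome model is supplied.
#' @param intercept,coefficients Logistic outcome model on the log-odds
#'   scale (ignored when `marginal_rate` is given). `coefficients` must have
#'   length 3.
#' @param study_intercept_sd Nonnegative SD (log-odds scale) of the
#'   study-level random intercept; only used by the logistic outcome form.
#' @param missing_rate Per-field MCAR missingness probability in \[0, 1\].
#'   Missingness is applied to four field groups: monofilament, pulses,
#'   outcome, and the ulcer/amputation history pair jointly (so that history
#'   behaves as a single field).
#' @param predictor_correlation Pairwise latent (tetrachoric-style) Gaussian
#'   correlation between the three predictors; default 0 (independent).
#' @param seed Integer seed; identical spec + seed gives identical output.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [development_cohort_specs()]
#' @export
#' @examples
#' cohort_spec("Abbott", n = 6478, prev_mono = 0.194, prev_pulse = 0.296,
#'             prev_hist = 0.047, marginal_rate = 0.044, seed = 1)
cohort_spec <- function(study_label, n,
                        prev_mono, prev_pulse, prev_hist,
                        marginal_rate = NULL,
                        intercept = NULL, coefficients = NULL,
                        study_intercept_sd = 0,
                        missing_rate = 0,
                        predictor_correlation = 0,
                        seed = NULL) {
  if (!is.character(study_label) || length(study_label) != 1L) {
    stop("`study_label` must be a single character string", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    stop(sprintf("`n` must be a positive integer (got %s)", format(n)),
         call. = FALSE)
  }
  check_prob(prev_mono, "prev_mono")
  check_prob(prev_pulse, "prev_pulse")
  check_prob(prev_hist, "prev_hist")
  check_prob(missing_rate, "missing_rate")
  if (!is.numeric(study_intercept_sd) || length(study_intercept_sd) != 1L ||
      is.na(study_intercept_sd) || study_intercept_sd < 0) {
    stop("`study_intercept_sd` must be a nonnegative real", call. = FALSE)
  }
  if (!is.numeric(predictor_correlation) || predictor_correlation < 0 ||
      predictor_correlation >= 1) {
    stop("`predictor_correlation` must be in [0, 1)", call. = FALSE)
  }

  if (is.null(marginal_rate)) {
    if (is.null(intercept) || is.null(coefficients)) {
      stop("supply either `marginal_rate` or both `intercept` and `coefficients`",
           call. = FALSE)
    }
    if (length(coefficients) != 3L || anyNA(coefficients)) {
      stop("`coefficients` must be three finite log-odds values ",
           "(monofilament, pulses, history)", call. = FALSE)
    }
    outcome_model <- list(type = "logistic",
                          intercept = as.numeric(intercept),
                          coefficients = as.numeric(coefficients))
  } else {
    check_prob(marginal_rate, "marginal_rate")
    outcome_model <- list(type = "marginal_rate", rate = as.numeric(marginal_rate))
  }

  structure(
    list(study_label = study_label,
         n = as.integer(n),
         prev_mono = prev_mono,
         prev_pulse = prev_pulse,
         prev_hist = prev_hist,
         outcome_model = outcome_model,
         study_intercept_sd = study_intercept_sd,
         missing_rate = missing_rate,
         predictor_correlation = predictor_correlation,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n = %d\n", x$study_label, x$n))
  cat(sprintf("  prevalences: mono %.3f, pulse %.3f, history %.3f\n",
              x$prev_mono, x$prev_pulse, x$prev_hist))
  if (x$outcome_model$type == "marginal_rate") {
    cat(sprintf("  outcome: marginal rate %.3f\n", x$outcome_model$rate))
  } else {
    cat(sprintf("  outcome: logistic, intercept %.3f, coefs (%s), sigma_u %.2f\n",
                x$outcome_model$intercept,
                paste(format(x$outcome_model$coefficients, digits = 3),
                      collapse = ", "),
                x$study_intercept_sd))
  }
  if (x$missing_rate > 0) {
    cat(sprintf("  missingness (MCAR, per field): %.3f\n", x$missing_rate))
  }
  invisible(x)
}

#' Read and write simulation scenarios as YAML
#'
#' A scenario file is a YAML list of cohort specifications, one mapping per
#' study, with keys matching the arguments of [cohort_spec()].
#'
#' @param path File path.
#' @param specs A list of `cohort_spec` objects (for writing).
#' @return `read_scenario()` returns a list of `cohort_spec` objects.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(entry) do.call(cohort_spec, entry))
}

#' @rdname read_scenario
#' @export
write_scenario <- function(specs, path) {
  entries <- lapply(specs, function(s) {
    out <- list(study_label = s$study_label, n = s$n,
                prev_mono = s$prev_mono, prev_pulse = s$prev_pulse,
                prev_hist = s$prev_hist)
    if (s$outcome_model$type == "marginal_rate") {
      out$marginal_rate <- s$outcome_model$rate
    } else {
      out$intercept <- s$outcome_model$intercept
      out$coefficients <- s$outcome_model$coefficients
    }
    out$study_intercept_sd <- s$study_intercept_sd
    out$missing_rate <- s$missing_rate
    out$predictor_correlation <- s$predictor_correlation
    if (!is.null(s$seed)) out$seed <- s$seed
    out
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
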