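#' Fit the pooled three-predictor logistic prognostic model
#'
#' Maximum-likelihood logistic regression of the 2-year ulcer outcome on the
#' coded predictors, fitted by iteratively reweighted least squares
#' ([stats::glm()] with `binomial` family; convergence tolerance `epsilon`).
#' All predictors are retained regardless of statistical significance.
#' Confidence intervals are Wald intervals on the log-odds scale,
#' exponentiated for odds ratios.
#'
#' @param records Harmonized, complete-case data frame.
#' @param predictors Character vector of predictor column names; default the
#'   three bedside predictors (monofilament insensitivity, any absent pulse,
#'   history of ulcer/amputation).
#' @param outcome Outcome column name (binary 0/1).
#' @param epsilon IRLS convergence tolerance on the relative deviance
#'   change; non-convergence is an error, never a silent result.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `prognostic_model` with components
#'   `intercept`, `coefficients` (named log-odds), `vcov`, `odds_ratios`
#'   (point and CI), `baseline_risk` (point and CI, the inverse-logit of the
#'   intercept), `n_used`, `n_events`, and the deviance-based fit summary.
#' @export
#' @examples
#' suite <- harmonize_records(simulate_development_suite(
#'   seed = 1, outcome_model = "logistic", study_intercept_sd = 0))
#' fit <- fit_logistic(suite)
#' fit
fit_logistic <- function(records,
                         predictors = c("mono_insensate", "pulses_absent", "history"),
                         outcome = "ulcer_2yr",
                         epsilon = 1e-10,
                         conf_level = 0.95) {
  cols <- c(predictors, outcome)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  dat <- records[cols]
  if (anyNA(dat)) {
    stop("records contain missing values; apply complete_case_filter() first",
         call. = FALSE)
  }
  y <- dat[[outcome]]
  check_binary_outcome(y, "outcomes")
  for (p in predictors) {
    if (length(unique(dat[[p]])) < 2L) {
      stop(sprintf("predictor `%s` is constant", p), call. = FALSE)
    }
  }

  form <- stats::as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")))
  # boundary-fit warnings are superseded by the explicit separation check below
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat,
               control = stats::glm.control(epsilon = epsilon, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) {
    stop("IRLS did not converge within 100 iterations", call. = FALSE)
  }
  # complete-separation diagnostic: runaway coefficient with huge SE
  se <- sqrt(diag(stats::vcov(fit)))
  runaway <- abs(stats::coef(fit)) > 12 & se > 10
  if (any(runaway[-1])) {
    stop(sprintf("complete or quasi-complete separation on predictor(s): %s",
                 paste(predictors[runaway[-1]], collapse = ", ")),
         call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  beta <- stats::coef(fit)
  coefs <- beta[-1]
  ci_lo <- beta - z * se
  ci_hi <- beta + z * se

  structure(
    list(
      intercept = unname(beta[1]),
      coefficients = stats::setNames(unname(coefs), predictors),
      vcov = stats::vcov(fit),
      odds_ratios = data.frame(
        predictor = predictors,
        or = exp(unname(coefs)),
        lower = exp(unname(ci_lo[-1])),
        upper = exp(unname(ci_hi[-1])),
        row.names = NULL
      ),
      baseline_risk = c(estimate = inv_logit(unname(beta[1])),
                        lower = inv_logit(unname(ci_lo[1])),
                        upper = inv_logit(unname(ci_hi[1]))),
      n_used = length(y),
      n_events = sum(y),
      null_deviance = fit$null.deviance,
      deviance = fit$deviance,
      df_model = length(predictors),
      predictors = predictors,
      outcome = outcome,
      conf_level = conf_level,
      formula = form
    ),
    class = "prognostic_model"
  )
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("<prognostic_model> n = %d, events = %d\n", x$n_used, x$n_events))
  cat(sprintf("  baseline risk: %.3f (%.0f%% CI %.3f to %.3f)\n",
              x$baseline_risk["estimate"], 100 * x$conf_level,
              x$baseline_risk["lower"], x$baseline_risk["upper"]))
  tab <- x$odds_ratios
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-16s beta = %6.3f   OR = %5.2f (%.2f to %.2f)\n",
                tab$predictor[i], x$coefficients[i],
                tab$or[i], tab$lower[i], tab$upper[i]))
  }
  if (!is.null(x$shrinkage)) {
    cat(sprintf("  bootstrap shrinkage factor: %.3f\n", x$shrinkage$s))
  }
  invisible(x)
}

#' Linear predictor of a prognostic model
#'
#' @param object A `prognostic_model`.
#' @param newdata Data frame carrying the model's predictor columns.
#' @param type `"link"` (log-odds) or `"response"` (probability).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.prognostic_model <- function(object, newdata,
                                     type = c("link", "response"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata[object$predictors])
  if (anyNA(x)) stop("newdata contains missing predictor values", call. = FALSE)
  eta <- object$intercept + drop(x %*% object$coefficients)
  if (type == "response") inv_logit(eta) else eta
}

#' Bootstrap uniform shrinkage factor
#'
#' Checks whether the sample size and event count are adequate for the
#' fitted model. For each bootstrap resample the model is refitted and the
#' calibration slope of the resample-model's linear predictor, evaluated on
#' the original data, is recorded; the shrinkage factor `s` is the mean
#' slope. Values near 1 indicate negligible overfitting. The heuristic
#' (likelihood-ratio chi-squared minus df) / chi-squared is reported as a
#' cross-check.
#'
#' @param model A fitted [fit_logistic()] model.
#' @param records The data the model was fitted on.
#' @param n_bootstrap Number of resamples (>= 50; default 500).
#' @param seed Integer seed for the resampling.
#' @return A list with `s`, its percentile CI, the per-resample `slopes`,
#'   `s_heuristic`, and `n_dropped` (non-finite refits, dropped; an error is
#'   raised if more than 20% drop).
#' @export
shrinkage_factor <- function(model, records, n_bootstrap = 500, seed = NULL) {
  stopifnot(inherits(model, "prognostic_model"))
  if (n_bootstrap < 50) stop("n_bootstrap must be >= 50", call. = FALSE)
  dat <- records[c(model$predictors, model$outcome)]
  if (anyNA(dat)) {
    stop("records contain missing values; apply complete_case_filter() first",
         call. = FALSE)
  }
  n <- nrow(dat)
  y <- dat[[model$outcome]]

  slopes <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- dat[idx, , drop = FALSE]
      if (sum(boot[[model$outcome]]) == 0 ||
          sum(boot[[model$outcome]]) == nrow(boot)) {
        return(NA_real_)
      }
      refit <- tryCatch(
        suppressWarnings(stats::glm(model$formula, family = stats::binomial(),
                                    data = boot)),
        error = function(e) NULL
      )
      if (is.null(refit) || !refit$converged) return(NA_real_)
      beta <- stats::coef(refit)
      if (any(!is.finite(beta))) return(NA_real_)
      lp <- beta[1] + drop(as.matrix(dat[model$predictors]) %*% beta[-1])
      if (stats::var(lp) == 0) return(NA_real_)
      cal <- suppressWarnings(stats::glm(y ~ lp, family = stats::binomial()))
      unname(stats::coef(cal)[2])
    }, numeric(1))
  })

  n_dropped <- sum(!is.finite(slopes))
  if (n_dropped > 0.2 * n_bootstrap) {
    stop(sprintf("%d of %d bootstrap refits were non-finite (> 20%%)",
                 n_dropped, n_bootstrap), call. = FALSE)
  }
  slopes <- slopes[is.finite(slopes)]
  chi2 <- model$null_deviance - model$deviance
  list(
    s = mean(slopes),
    ci = unname(stats::quantile(slopes, c(0.025, 0.975))),
    slopes = slopes,
    s_heuristic = (chi2 - model$df_model) / chi2,
    n_dropped = n_dropped
  )
}

#' Convert prognostic-model coefficients to integer score weights
#'
#' Each coefficient is rounded to the nearest integer (ties away from
#' zero), yielding the score weight of its predictor. With the published
#' coefficients (1.11, 0.70, 1.95) this gives weights (1, 1, 2) and a score
#' range of 0 to 4. A weight that rounds to 0 triggers a warning: that
#' predictor contributes nothing to the score.
#'
#' @param model A `prognostic_model`, or a bare numeric vector of
#'   coefficients.
#' @return Named integer vector of weights.
#' @export
#' @examples
#' convert_to_cpr(c(mono = 1.11, pulse = 0.70, history = 1.95))  # 1 1 2
convert_to_cpr <- function(model) {
  coefs <- if (inherits(model, "prognostic_model")) model$coefficients else model
  if (any(coefs <= 0)) {
    stop("score conversion requires positive coefficients", call. = FALSE)
  }
  w <- as.integer(round_half_away(coefs))
  names(w) <- names(coefs)
  if (any(w == 0L)) {
    warning(sprintf("weight 0 for predictor(s): %s (no contribution to the score)",
                    paste(names(w)[w == 0L], collapse = ", ")))
  }
  w
}

#' Compute integer CPR scores
#'
#' The score is the weighted sum of the three binary predictors; with the
#' published weights (1 for monofilament insensitivity, 1 for any absent
#' pulse, 2 for history of ulcer/amputation) scores run from 0 to 4.
#' Scores are defined on complete cases only: any missing predictor is an
#' error.
#'
#' @param records Harmonized data frame (or a single-row list) carrying the
#'   predictor columns named by `weights`.
#' @param weights Named integer weights from [convert_to_cpr()].
#' @return Integer vector of scores.
#' @export
#' @examples
#' cpr_score(data.frame(mono_insensate = 1, pulses_absent = 0, history = 1),
#'           c(mono_insensate = 1L, pulses_absent = 1L, history = 2L))  # 3
cpr_score <- function(records, weights) {
  x <- as.matrix(as.data.frame(records)[names(weights)])
  if (anyNA(x)) {
    stop("missing predictor value(s): scores are computed on complete cases only",
         call. = FALSE)
  }
  if (!all(x %in% c(0, 1))) {
    stop("predictors must be coded 0/1", call. = FALSE)
  }
  as.integer(drop(x %*% weights))
}

#' Fit the score logistic model, optionally with study-level random intercepts
#'
#' Refits the modelling procedure with the integer CPR score as the only
#' predictor. With two or more studies a random-intercept logistic model is
#' fitted by adaptive Gauss-Hermite quadrature ([lme4::glmer()]), giving the
#' between-study intercept SD used for population-average (marginal) risk
#' estimation. With a single study the model reduces to ordinary logistic
#' regression and the SD is fixed at 0.
#'
#' @param scores Integer score per participant.
#' @param outcomes Binary 0/1 outcome per participant.
#' @param study Optional study label per participant.
#' @param score_range Attainable score range, as `c(min, max)`; defaults to
#'   the observed range.
#' @param nagq Number of adaptive quadrature points for the random-intercept
#'   fit.
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `score_model`: intercept `alpha` (log-odds at
#'   score 0), per-point log-odds ratio `gamma`, their 2x2 `vcov`,
#'   between-study `sigma_u`, and bookkeeping fields.
#' @export
fit_score_model <- function(scores, outcomes, study = NULL,
                            score_range = range(scores),
                            nagq = 10, conf_level = 0.95) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(outcomes)) {
    stop("scores and outcomes must be complete", call. = FALSE)
  }
  check_binary_outcome(outcomes)
  if (length(unique(scores)) < 2L) {
    stop("at least two distinct score values are required", call. = FALSE)
  }

  multi_study <- !is.null(study) && length(unique(study)) > 1L
  if (multi_study) {
    dat <- data.frame(y = outcomes, score = scores, study = factor(study))
    fit <- lme4::glmer(y ~ score + (1 | study), data = dat,
                       family = stats::binomial(), nAGQ = nagq)
    if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
      stop(sprintf("adaptive quadrature fit did not converge (optimizer code %d): %s",
                   fit@optinfo$conv$opt,
                   paste(unlist(fit@optinfo$message), collapse = "; ")),
           call. = FALSE)
    }
    beta <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    sigma_u <- sqrt(unname(lme4::VarCorr(fit)$study[1]))
  } else {
    fit <- stats::glm(outcomes ~ scores, family = stats::binomial())
    if (!fit$converged) stop("score-model IRLS did not converge", call. = FALSE)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    sigma_u <- 0
  }

  score_model(alpha = unname(beta[1]), gamma = unname(beta[2]),
              sigma_u = sigma_u, vcov = unname(vc),
              score_range = score_range,
              n_used = length(outcomes), n_events = sum(outcomes),
              conf_level = conf_level)
}

#' Construct a score model from known parameters
#'
#' Builds a `score_model` directly from its parameters — for example the
#' published baseline risk and per-point odds ratio of an existing rule —
#' so that per-score risks can be computed without refitting.
#'
#' @param alpha Intercept: log-odds of the outcome at score 0.
#' @param gamma Per-point log-odds ratio (`exp(gamma)` is the odds ratio per
#'   score point).
#' @param sigma_u Between-study intercept SD (log-odds scale); 0 gives the
#'   ordinary (conditional) logistic model.
#' @param vcov Optional 2x2 covariance matrix of `(alpha, gamma)`; needed
#'   for confidence intervals.
#' @param score_range Attainable scores, as `c(min, max)`.
#' @param n_used,n_events Optional sample bookkeeping.
#' @param conf_level Confidence level used for intervals.
#' @return An object of class `score_model`.
#' @export
#' @examples
#' sm <- score_model(alpha = logit(0.024), gamma = log(2.57))
#' population_average_risk(sm, 1)
score_model <- function(alpha, gamma, sigma_u = 0, vcov = NULL,
                        score_range = c(0, 4),
                        n_used = NA_integer_, n_events = NA_integer_,
                        conf_level = 0.95) {
  stopifnot(is.numeric(alpha), is.numeric(gamma), sigma_u >= 0,
            length(score_range) == 2L, score_range[1] <= score_range[2])
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    stopifnot(all(dim(vcov) == c(2L, 2L)))
  }
  structure(
    list(alpha = alpha, gamma = gamma, sigma_u = sigma_u, vcov = vcov,
         score_range = as.integer(score_range),
         n_used = n_used, n_events = n_events, conf_level = conf_level),
    class = "score_model"
  )
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("<score_model> alpha = %.3f (baseline risk %.3f), per-point OR = %.2f\n",
              x$alpha, inv_logit(x$alpha), exp(x$gamma)))
  cat(sprintf("  between-study intercept SD (sigma_u): %.3f; scores %d to %d\n",
              x$sigma_u, x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' Population-average (marginal) outcome probability at a score
#'
#' The cluster-specific score model gives the outcome probability for a
#' study with a given baseline; the population-average probability
#' marginalizes over the between-study intercept distribution:
#' \deqn{p_k = \int \mathrm{logit}^{-1}(\alpha + \gamma k + u)\,
#'   \varphi(u; \sigma_u)\, du,}
#' evaluated by Gauss-Hermite quadrature. With `sigma_u = 0` this reduces
#' exactly to the conditional inverse-logit. Confidence intervals apply the
#' same marginalization to the Wald interval endpoints of
#' \eqn{\alpha + \gamma k}; the analytic attenuation approximation (divide
#' the linear predictor by \eqn{\sqrt{1 + 0.346\,\sigma_u^2}}) is available
#' as an alternative.
#'
#' @param model A `score_model`.
#' @param k Integer score (scalar or vector) within the model's score range.
#' @param nodes Number of quadrature nodes (>= 30 recommended).
#' @param method `"quadrature"` (default) or `"attenuation"`.
#' @return A data frame with columns `score`, `probability`, and (when the
#'   model carries a covariance matrix) `lower` and `upper`.
#' @export
population_average_risk <- function(model, k, nodes = 40,
                                    method = c("quadrature", "attenuation")) {
  stopifnot(inherits(model, "score_model"))
  method <- match.arg(method)
  if (any(k < model$score_range[1] | k > model$score_range[2])) {
    stop(sprintf("score out of range [%d, %d]",
                 model$score_range[1], model$score_range[2]), call. = FALSE)
  }
  eta <- model$alpha + model$gamma * k
  marg <- function(e) {
    if (method == "quadrature") {
      marginal_inv_logit(e, model$sigma_u, nodes = nodes)
    } else {
      inv_logit(e / sqrt(1 + 0.346 * model$sigma_u^2))
    }
  }
  out <- data.frame(score = k, probability = marg(eta))
  if (!is.null(model$vcov)) {
    z <- stats::qnorm(1 - (1 - model$conf_level) / 2)
    se <- sqrt(model$vcov[1, 1] + k^2 * model$vcov[2, 2] +
                 2 * k * model$vcov[1, 2])
    out$lower <- marg(eta - z * se)
    out$upper <- marg(eta + z * se)
  }
  out
}

#' Build the per-score population-average risk table
#'
#' For each attainable score: the number of participants at that score, the
#' marginal outcome probability, and its confidence interval. With a
#' positive per-point log-odds ratio the probabilities are strictly
#' increasing in score.
#'
#' @param model A `score_model`.
#' @param scores Integer scores of the development participants (used for
#'   the per-score counts).
#' @param nodes,method Passed to [population_average_risk()].
#' @return A data frame with columns `score`, `n`, `probability`, and when
#'   available `lower`, `upper`.
#' @export
build_risk_table <- function(model, scores, nodes = 40,
                             method = c("quadrature", "attenuation")) {
  stopifnot(inherits(model, "score_model"))
  ks <- seq(model$score_range[1], model$score_range[2])
  risks <- population_average_risk(model, ks, nodes = nodes, method = method)
  counts <- as.integer(table(factor(scores, levels = ks)))
  out <- cbind(data.frame(score = ks, n = counts),
               risks[setdiff(names(risks), "score")])
  rownames(out) <- NULL
  out
}

#' Develop a clinical prediction rule end-to-end
#'
#' Convenience wrapper: fits the prognostic model, converts the
#' coefficients to integer weights, scores the development data, fits the
#' score model (with study-level random intercepts when several studies are
#' present), and assembles the population-average risk table.
#'
#' @param records Harmonized, complete-case data frame (with `study_label`
#'   when multi-study).
#' @param predictors,outcome Column names, as in [fit_logistic()].
#' @param n_bootstrap Bootstrap resamples for the shrinkage check; 0 skips
#'   it.
#' @param seed Seed for the bootstrap.
#' @param nagq,nodes Quadrature settings for the score model and the
#'   marginalization.
#' @return An object of class `cpr_rule`: `weights`, `score_range`,
#'   `score_model`, `risk_table`, plus the underlying `prognostic_model`.
#' @export
#' @examples
#' suite <- harmonize_records(simulate_development_suite(
#'   seed = 1, outcome_model = "logistic", study_intercept_sd = 0.3))
#' rule <- develop_cpr(suite, n_bootstrap = 0)
#' rule$risk_table
develop_cpr <- function(records,
                        predictors = c("mono_insensate", "pulses_absent", "history"),
                        outcome = "ulcer_2yr",
                        n_bootstrap = 500, seed = NULL,
                        nagq = 10, nodes = 40) {
  model <- fit_logistic(records, predictors = predictors, outcome = outcome)
  if (n_bootstrap > 0) {
    model$shrinkage <- shrinkage_factor(model, records,
                                        n_bootstrap = n_bootstrap, seed = seed)
  }
  weights <- convert_to_cpr(model)
  scores <- cpr_score(records, weights)
  study <- if ("study_label" %in% names(records)) records$study_label else NULL
  sm <- fit_score_model(scores, records[[outcome]], study = study,
                        score_range = c(0L, sum(weights)), nagq = nagq)
  structure(
    list(weights = weights,
         score_range = c(0L, sum(weights)),
         score_model = sm,
         heterogeneity_sd = sm$sigma_u,
         risk_table = build_risk_table(sm, scores, nodes = nodes),
         prognostic_model = model),
    class = "cpr_rule"
  )
}

#' @export
print.cpr_rule <- function(x, ...) {
  cat("<cpr_rule> integer scoring system\n")
  for (nm in names(x$weights)) {
    cat(sprintf("  %-16s +%d point%s\n", nm, x$weights[[nm]],
                if (x$weights[[nm]] == 1) "" else "s"))
  }
  cat(sprintf("  scores %d to %d; per-point OR %.2f; sigma_u %.3f\n",
              x$score_range[1], x$score_range[2],
              exp(x$score_model$gamma), x$heterogeneity_sd))
  cat("  population-average risk by score:\n")
  print(x$risk_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export models and tables as JSON / CSV
#'
#' `write_model_json()` serializes a `prognostic_model` or `cpr_rule` to a
#' JSON document; `write_risk_table_csv()` writes the per-score risk table
#' as CSV (score, n, probability, CI bounds).
#'
#' @param x A `prognostic_model` or `cpr_rule`.
#' @param path Output file path.
#' @export
write_model_json <- function(x, path) {
  payload <- if (inherits(x, "cpr_rule")) {
    list(weights = as.list(x$weights),
         score_range = x$score_range,
         score_model = list(alpha = x$score_model$alpha,
                            gamma = x$score_model$gamma,
                            per_point_or = exp(x$score_model$gamma),
                            sigma_u = x$score_model$sigma_u,
                            vcov = x$score_model$vcov),
         risk_table = x$risk_table,
         prognostic_model = list(
           intercept = x$prognostic_model$intercept,
           coefficients = as.list(x$prognostic_model$coefficients),
           covariance = unname(as.matrix(x$prognostic_model$vcov)),
           odds_ratios = x$prognostic_model$odds_ratios,
           baseline_risk = as.list(x$prognostic_model$baseline_risk),
           n_used = x$prognostic_model$n_used,
           n_events = x$prognostic_model$n_events))
  } else if (inherits(x, "prognostic_model")) {
    list(intercept = x$intercept,
         coefficients = as.list(x$coefficients),
         covariance = unname(as.matrix(x$vcov)),
         odds_ratios = x$odds_ratios,
         baseline_risk = as.list(x$baseline_risk),
         n_used = x$n_used, n_events = x$n_events,
         shrinkage = if (!is.null(x$shrinkage)) {
           list(s = x$shrinkage$s, ci = x$shrinkage$ci,
                s_heuristic = x$shrinkage$s_heuristic)
         })
  } else {
    stop("x must be a prognostic_model or cpr_rule", call. = FALSE)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @param risk_table A risk table from [build_risk_table()].
#' @rdname write_model_json
#' @export
write_risk_table_csv <- function(risk_table, path) {
  utils::write.csv(risk_table, path, row.names = FALSE)
  invisible(path)
}
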