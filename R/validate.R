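#' C-statistic (concordance / AUROC) with DeLong confidence interval
#'
#' The probability that a randomly chosen participant who developed an
#' ulcer is ranked above a randomly chosen participant who did not, with
#' ties counted one half — the Mann-Whitney / rank formulation, exact over
#' all event-by-non-event pairs. The confidence interval uses DeLong's
#' placement-based variance estimator, which is deterministic (no
#' resampling).
#'
#' @param scores Numeric risk scores or predicted risks (any strictly
#'   increasing transform gives the same C-statistic).
#' @param outcomes Binary 0/1 outcomes; at least one event and one
#'   non-event.
#' @param conf_level Confidence level.
#' @return A list with `c` (the C-statistic), `se`, `lower`, `upper`,
#'   `n_events`, `n_nonevents`.
#' @export
#' @examples
#' c_statistic(c(1, 2, 2, 3), c(0, 0, 1, 1))$c  # 0.875
c_statistic <- function(scores, outcomes, conf_level = 0.95) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(outcomes)) {
    stop("scores and outcomes must be complete", call. = FALSE)
  }
  check_binary_outcome(outcomes)
  x <- scores[outcomes == 1]  # events
  y <- scores[outcomes == 0]  # non-events
  m <- length(x)
  n <- length(y)

  # midrank formulation: C = (sum of event ranks - m(m+1)/2) / (m n)
  r <- rank(c(x, y), ties.method = "average")
  cstat <- (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)

  # DeLong placements
  v10 <- vapply(x, function(xi) (sum(y < xi) + 0.5 * sum(y == xi)) / n,
                numeric(1))
  v01 <- vapply(y, function(yj) (sum(x > yj) + 0.5 * sum(x == yj)) / m,
                numeric(1))
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(c = cstat, se = se,
       lower = max(0, cstat - z * se),
       upper = min(1, cstat + z * se),
       n_events = m, n_nonevents = n)
}

#' Calibration slope and calibration-in-the-large
#'
#' The calibration slope is the coefficient of the model's linear predictor
#' in a logistic refit on the validation outcomes (1 = neither over- nor
#' under-fitted). Calibration-in-the-large is the intercept of a logistic
#' refit with the linear predictor as a fixed offset (0 = correct average
#' risk). Both carry Wald confidence intervals.
#'
#' @param lp Linear predictor (log-odds) per participant. Must vary: raw
#'   integer scores should first be converted to log-odds through a
#'   [score_model()].
#' @param outcomes Binary 0/1 outcomes.
#' @param conf_level Confidence level.
#' @return A list with components `slope` and `itl`, each
#'   `c(estimate, lower, upper)`.
#' @export
calibration_metrics <- function(lp, outcomes, conf_level = 0.95) {
  if (length(lp) != length(outcomes)) {
    stop("lp and outcomes must have equal length", call. = FALSE)
  }
  if (any(!is.finite(lp))) {
    stop("linear predictors must be finite", call. = FALSE)
  }
  check_binary_outcome(outcomes)
  if (stats::var(lp) == 0) {
    stop("constant linear predictor: calibration slope is unidentifiable",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  fit_slope <- stats::glm(outcomes ~ lp, family = stats::binomial())
  b <- unname(stats::coef(fit_slope)[2])
  se_b <- sqrt(stats::vcov(fit_slope)[2, 2])

  fit_itl <- stats::glm(outcomes ~ 1 + offset(lp), family = stats::binomial())
  a <- unname(stats::coef(fit_itl)[1])
  se_a <- sqrt(stats::vcov(fit_itl)[1, 1])

  list(slope = c(estimate = b, lower = b - z * se_b, upper = b + z * se_b),
       itl = c(estimate = a, lower = a - z * se_a, upper = a + z * se_a))
}

#' Grouped observed-versus-predicted calibration rows
#'
#' One row per observed score value: participant count, observed event
#' proportion with an exact Clopper-Pearson confidence interval (group
#' counts at high scores are small), and the risk table's predicted
#' probability — the data behind a grouped calibration plot. Score levels
#' with no participants are omitted with a message.
#'
#' @param scores Integer scores per participant.
#' @param outcomes Binary 0/1 outcomes.
#' @param risk_table Risk table from [build_risk_table()] covering every
#'   observed score.
#' @param conf_level Confidence level for the exact binomial interval.
#' @return Data frame with columns `score`, `n`, `observed`, `lower`,
#'   `upper`, `predicted`.
#' @export
calibration_groups <- function(scores, outcomes, risk_table,
                               conf_level = 0.95) {
  if (length(scores) != length(outcomes)) {
    stop("scores and outcomes must have equal length", call. = FALSE)
  }
  observed_levels <- sort(unique(scores))
  missing_from_table <- setdiff(observed_levels, risk_table$score)
  if (length(missing_from_table)) {
    stop(sprintf("risk table lacks observed score(s): %s",
                 paste(missing_from_table, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(risk_table$score, observed_levels)
  if (length(absent)) {
    message(sprintf("no participants at score(s) %s; row(s) omitted",
                    paste(absent, collapse = ", ")))
  }
  rows <- lapply(observed_levels, function(k) {
    idx <- scores == k
    nk <- sum(idx)
    ev <- sum(outcomes[idx])
    ci <- stats::binom.test(ev, nk, conf.level = conf_level)$conf.int
    data.frame(score = k, n = nk, observed = ev / nk,
               lower = ci[1], upper = ci[2],
               predicted = risk_table$probability[risk_table$score == k])
  })
  do.call(rbind, rows)
}

#' Receiver operating characteristic points for a discrete score
#'
#' One point per distinct threshold between observed score values (treat
#' score >= threshold as test-positive), plus the (0,0) and (1,1) anchors.
#' The trapezoidal area under these points equals the tie-corrected
#' C-statistic.
#'
#' @inheritParams c_statistic
#' @return Data frame with columns `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), ordered from (0,0) to (1,1).
#' @export
roc_points <- function(scores, outcomes) {
  check_binary_outcome(outcomes)
  m <- sum(outcomes == 1)
  n <- sum(outcomes == 0)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thresholds, function(t) {
    pos <- scores >= t
    c(fpr = sum(pos & outcomes == 0) / n,
      tpr = sum(pos & outcomes == 1) / m)
  }, numeric(2)))
  out <- rbind(data.frame(fpr = 0, tpr = 0),
               as.data.frame(pts))
  rownames(out) <- NULL
  out
}

# trapezoidal area under ROC points; equals c_statistic for discrete scores
trapezoid_auc <- function(points) {
  sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                            utils::tail(points$tpr, -1)) / 2)
}

#' Externally validate a clinical prediction rule
#'
#' Computes discrimination (C-statistic with DeLong CI), calibration
#' (slope and calibration-in-the-large of the score model's linear
#' predictor, alpha + gamma * score) and grouped calibration rows on a new
#' dataset. Raw integer scores are never validated directly: the score
#' model supplies the log-odds scale the calibration metrics are defined
#' on.
#'
#' @param scores Integer CPR scores in the validation data.
#' @param outcomes Binary 0/1 outcomes.
#' @param model A `score_model` (or a `cpr_rule`, whose score model and
#'   risk table are used).
#' @param risk_table Risk table for the grouped calibration; defaults to
#'   the rule's table when `model` is a `cpr_rule`.
#' @param conf_level Confidence level throughout.
#' @return An object of class `validation_report`.
#' @export
validate_cpr <- function(scores, outcomes, model, risk_table = NULL,
                         conf_level = 0.95) {
  if (inherits(model, "cpr_rule")) {
    if (is.null(risk_table)) risk_table <- model$risk_table
    model <- model$score_model
  }
  if (!inherits(model, "score_model")) {
    stop("supply a score_model (or cpr_rule); raw integer scores cannot be ",
         "validated directly — convert them to log-odds first", call. = FALSE)
  }
  lp <- model$alpha + model$gamma * scores
  cs <- c_statistic(scores, outcomes, conf_level = conf_level)
  cal <- calibration_metrics(lp, outcomes, conf_level = conf_level)
  groups <- if (!is.null(risk_table)) {
    calibration_groups(scores, outcomes, risk_table, conf_level = conf_level)
  }
  structure(
    list(c_statistic = cs,
         calibration_slope = cal$slope,
         calibration_itl = cal$itl,
         groups = groups,
         n_used = length(outcomes),
         n_events = sum(outcomes),
         conf_level = conf_level),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> n = %d, events = %d\n", x$n_used, x$n_events))
  cat(sprintf("  C-statistic: %.3f (%.0f%% CI %.3f to %.3f)\n",
              x$c_statistic$c, 100 * x$conf_level,
              x$c_statistic$lower, x$c_statistic$upper))
  cat(sprintf("  calibration slope: %.3f (%.3f to %.3f)\n",
              x$calibration_slope["estimate"], x$calibration_slope["lower"],
              x$calibration_slope["upper"]))
  cat(sprintf("  calibration-in-the-large: %.3f (%.3f to %.3f)\n",
              x$calibration_itl["estimate"], x$calibration_itl["lower"],
              x$calibration_itl["upper"]))
  if (!is.null(x$groups)) {
    cat("  observed vs predicted by score:\n")
    print(x$groups, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @export
write_validation_json <- function(report, path) {
  payload <- list(
    c_statistic = report$c_statistic,
    calibration_slope = as.list(report$calibration_slope),
    calibration_itl = as.list(report$calibration_itl),
    groups = report$groups,
    n_used = report$n_used,
    n_events = report$n_events
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot a grouped calibration curve
#'
#' Observed event proportion (with exact binomial CI bars) against the
#' predicted probability for each score group, with the identity line for
#' reference.
#'
#' @param groups Data frame from [calibration_groups()] (or a
#'   `validation_report`).
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_calibration <- function(groups, file = NULL, ...) {
  if (inherits(groups, "validation_report")) groups <- groups$groups
  if (is.null(groups)) stop("no calibration groups available", call. = FALSE)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900, res = 150)
    on.exit(grDevices::dev.off())
  }
  lim <- c(0, max(groups$upper, groups$predicted) * 1.05)
  graphics::plot(groups$predicted, groups$observed, xlim = lim, ylim = lim,
                 pch = 19, xlab = "Predicted probability of ulcer by 2 years",
                 ylab = "Observed proportion", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  graphics::segments(groups$predicted, groups$lower,
                     groups$predicted, groups$upper)
  invisible(groups)
}
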