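#' Net benefit of a treatment strategy at a threshold probability
#'
#' Net benefit weighs true positives against false positives at the odds of
#' the threshold probability:
#' \deqn{NB(p_t) = \frac{TP}{n} - \frac{FP}{n}\cdot\frac{p_t}{1 - p_t},}
#' where TP is the number of treated participants who developed an ulcer
#' and FP the number treated who did not. Treat-none scores 0 everywhere;
#' no strategy can exceed the event prevalence.
#'
#' @param outcomes Binary 0/1 outcomes.
#' @param treat_flags Logical (or 0/1) vector: who the strategy treats.
#' @param p_t Threshold probability, strictly inside (0, 1).
#' @return Net benefit (scalar).
#' @export
#' @examples
#' net_benefit(c(1, 0, 0, 1), c(TRUE, TRUE, FALSE, FALSE), 0.06)
net_benefit <- function(outcomes, treat_flags, p_t) {
  if (!is.numeric(p_t) || length(p_t) != 1L || is.na(p_t) ||
      p_t <= 0 || p_t >= 1) {
    stop(sprintf("`p_t` must lie strictly in (0, 1) (got %s)", format(p_t)),
         call. = FALSE)
  }
  if (length(outcomes) != length(treat_flags)) {
    stop("outcomes and treat_flags must have equal length", call. = FALSE)
  }
  if (!all(outcomes %in% c(0, 1))) {
    stop("outcomes must be coded 0/1", call. = FALSE)
  }
  treat <- as.logical(treat_flags)
  n <- length(outcomes)
  tp <- sum(treat & outcomes == 1)
  fp <- sum(treat & outcomes == 0)
  tp / n - (fp / n) * (p_t / (1 - p_t))
}

#' Decision curve: net benefit across a threshold grid
#'
#' Compares three strategies on a grid of threshold probabilities: treat
#' everybody, treat nobody, and treat guided by predicted risk (treat when
#' predicted risk >= the threshold; the closed lower bound ensures that a
#' cut placed exactly at a risk-table value treats that score group).
#'
#' @param outcomes Binary 0/1 outcomes.
#' @param predicted_risks Predicted outcome probability per participant, in
#'   (0, 1).
#' @param thresholds Strictly increasing grid inside (0, 1); the default
#'   0.005 to 0.30 in steps of 0.005 spans the clinically actionable low
#'   range of 2-year ulcer risks.
#' @return An object of class `decision_curve`: a data frame-backed list
#'   with `thresholds`, `nb_model`, `nb_all`, `nb_none`, and `prevalence`.
#' @export
#' @examples
#' reg <- simulate_score_register(2000, logit(0.024), log(2.57), seed = 3)
#' risk <- inv_logit(reg$lp)
#' dc <- decision_curve(reg$ulcer_2yr, risk)
#' head(as.data.frame(dc))
decision_curve <- function(outcomes, predicted_risks,
                           thresholds = seq(0.005, 0.30, by = 0.005)) {
  if (length(outcomes) != length(predicted_risks)) {
    stop("outcomes and predicted_risks must have equal length", call. = FALSE)
  }
  if (any(predicted_risks <= 0 | predicted_risks >= 1)) {
    stop("predicted risks must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds >= 1) ||
      any(diff(thresholds) <= 0)) {
    stop("thresholds must be strictly increasing within (0, 1)", call. = FALSE)
  }
  nb_model <- vapply(thresholds, function(pt) {
    net_benefit(outcomes, predicted_risks >= pt, pt)
  }, numeric(1))
  nb_all <- vapply(thresholds, function(pt) {
    net_benefit(outcomes, rep(TRUE, length(outcomes)), pt)
  }, numeric(1))
  structure(
    list(thresholds = thresholds,
         nb_model = nb_model,
         nb_all = nb_all,
         nb_none = rep(0, length(thresholds)),
         prevalence = mean(outcomes)),
    class = "decision_curve"
  )
}

#' @export
as.data.frame.decision_curve <- function(x, ...) {
  data.frame(threshold = x$thresholds, nb_model = x$nb_model,
             nb_all = x$nb_all, nb_none = x$nb_none)
}

#' @export
print.decision_curve <- function(x, ...) {
  cat(sprintf("<decision_curve> %d thresholds in [%.3f, %.3f], prevalence %.3f\n",
              length(x$thresholds), min(x$thresholds), max(x$thresholds),
              x$prevalence))
  win <- x$nb_model >= pmax(x$nb_all, x$nb_none)
  if (any(win)) {
    cat(sprintf("  model strategy weakly dominates on [%.3f, %.3f]\n",
                min(x$thresholds[win]), max(x$thresholds[win])))
  }
  invisible(x)
}

#' Recommend the referral score threshold from a decision curve
#'
#' At a threshold probability between the table risks of scores k-1 and k,
#' the risk-guided strategy treats exactly the participants scoring k or
#' more; so each score owns an interval of the decision curve. The
#' recommended referral score is the smallest k whose interval (clipped to
#' the clinically relevant threshold range) is non-empty and on which the
#' risk-guided strategy (i) is never worse than treat-all or treat-none and
#' (ii) is strictly better than treat-all somewhere — i.e. a genuine
#' "treat some" improvement, which excludes the trivial treat-everyone cut
#' at score 0. Returns an explicit "no recommendation" result (never an
#' error) when no score's interval qualifies, e.g. for a flat risk table.
#'
#' @param curve A [decision_curve()] computed with predicted risks taken
#'   from `risk_table`.
#' @param risk_table Risk table from [build_risk_table()].
#' @param threshold_range Clinically relevant threshold probabilities;
#'   default 0.02 to 0.15, bracketing plausible referral thresholds for
#'   preventative foot care.
#' @return A list with `recommended` (logical), `score`, `risk` (the
#'   score's table risk, i.e. the treat/don't-treat cut), and the grid
#'   points examined per score.
#' @export
recommend_threshold <- function(curve, risk_table,
                                threshold_range = c(0.02, 0.15)) {
  stopifnot(inherits(curve, "decision_curve"),
            length(threshold_range) == 2L,
            threshold_range[1] < threshold_range[2])
  eps <- 1e-12
  tab <- risk_table[order(risk_table$score), ]
  for (i in seq_len(nrow(tab))) {
    lo <- if (i == 1) -Inf else tab$probability[i - 1]
    hi <- tab$probability[i]
    in_interval <- curve$thresholds > lo & curve$thresholds <= hi &
      curve$thresholds >= threshold_range[1] &
      curve$thresholds <= threshold_range[2]
    if (!any(in_interval)) next
    nb_m <- curve$nb_model[in_interval]
    nb_a <- curve$nb_all[in_interval]
    never_worse <- all(nb_m >= nb_a - eps) && all(nb_m >= -eps)
    strictly_better <- any(nb_m > nb_a + eps)
    if (never_worse && strictly_better) {
      return(list(recommended = TRUE,
                  score = tab$score[i],
                  risk = hi,
                  grid = curve$thresholds[in_interval]))
    }
  }
  list(recommended = FALSE, score = NA_integer_, risk = NA_real_,
       grid = numeric(0))
}

#' Plot a decision curve
#'
#' Net benefit against threshold probability for the model-guided,
#' treat-all, and treat-none strategies.
#'
#' @param x A `decision_curve`.
#' @param file Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.decision_curve <- function(x, file = NULL, ...) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900, res = 150)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(c(x$nb_model, x$nb_all, 0))
  graphics::plot(x$thresholds, x$nb_model, type = "l", lwd = 2, ylim = ylim,
                 xlab = "Threshold probability", ylab = "Net benefit", ...)
  graphics::lines(x$thresholds, x$nb_all, lty = 2, col = "grey40")
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", lwd = c(2, 1, 1), lty = c(1, 2, 3),
                   col = c("black", "grey40", "black"),
                   legend = c("CPR-guided", "treat all", "treat none"),
                   bty = "n")
  invisible(x)
}

#' Write a decision curve as CSV
#'
#' @param curve A `decision_curve`.
#' @param path Output file path.
#' @export
write_decision_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
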