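# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, closed forms, and
# Monte Carlo stand in for the implementations they check.

# C-statistic by explicit enumeration of all event x non-event pairs.
brute_force_c <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  ne <- scores[outcomes == 0]
  cmp <- outer(ev, ne, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Net benefit by explicit confusion-matrix counting.
brute_force_nb <- function(outcomes, treat, p_t) {
  n <- length(outcomes)
  tp <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (treat[i] && outcomes[i] == 1) tp <- tp + 1
    if (treat[i] && outcomes[i] == 0) fp <- fp + 1
  }
  tp / n - fp / n * p_t / (1 - p_t)
}

# Three-valued coding oracles as literal truth tables over symbols.
oracle_mono <- function(sites) {
  if (any(sites == "not_felt", na.rm = TRUE)) return(1L)
  if (all(is.na(sites))) return(NA_integer_)
  0L  # at least one felt, none insensate (permissive rule)
}
oracle_pulses <- function(pulses) {
  if (any(pulses == "absent", na.rm = TRUE)) return(1L)
  if (any(is.na(pulses))) return(NA_integer_)
  0L
}
oracle_or3 <- function(a, b) {
  if (isTRUE(a == 1) || isTRUE(b == 1)) return(1L)
  if (isTRUE(a == 0) && isTRUE(b == 0)) return(0L)
  NA_integer_
}

# 2x2 single-predictor dataset: exposed a events / b non-events,
# unexposed c events / d non-events.
make_2x2 <- function(a, b, c, d) {
  data.frame(x = rep(c(1, 0), c(a + b, c + d)),
             ulcer_2yr = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

# Simulate a complete three-predictor cohort straight from a logistic model
# (independent of simulate_cohort) for parameter-recovery checks.
sim_logistic_cohort <- function(n, intercept, coefs, prev = c(0.2, 0.27, 0.09)) {
  x1 <- rbinom(n, 1, prev[1])
  x2 <- rbinom(n, 1, prev[2])
  x3 <- rbinom(n, 1, prev[3])
  p <- plogis(intercept + coefs[1] * x1 + coefs[2] * x2 + coefs[3] * x3)
  data.frame(mono_insensate = x1, pulses_absent = x2, history = x3,
             ulcer_2yr = rbinom(n, 1, p))
}
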