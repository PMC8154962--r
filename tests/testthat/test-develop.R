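test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- make_2x2(10, 40, 5, 45)
  fit <- fit_logistic(d, predictors = "x")
  expect_equal(unname(fit$coefficients), log((10 * 45) / (40 * 5)),
               tolerance = 1e-6)
  expect_equal(fit$intercept, log(5 / 45), tolerance = 1e-6)

  # random saturated instances against the ad/bc closed form
  set.seed(99)
  for (i in 1:20) {
    cells <- sample(3:60, 4, replace = TRUE)
    d <- make_2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fit_logistic(d, predictors = "x")
    expect_equal(unname(fit$coefficients),
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-6)
  }
})

test_that("odds ratios are exactly exp(coefficients) with ordered CIs", {
  suite <- harmonize_records(simulate_development_suite(
    seed = 2, outcome_model = "logistic", study_intercept_sd = 0))
  fit <- fit_logistic(suite)
  expect_equal(fit$odds_ratios$or, unname(exp(fit$coefficients)))
  expect_true(all(fit$odds_ratios$lower < fit$odds_ratios$or))
  expect_true(all(fit$odds_ratios$or < fit$odds_ratios$upper))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-12))
  expect_gt(fit$baseline_risk["estimate"], 0)
  expect_lt(fit$baseline_risk["estimate"], 1)
})

test_that("degenerate inputs raise named errors", {
  d <- data.frame(x = rbinom(50, 1, 0.5), ulcer_2yr = 0)
  expect_error(fit_logistic(d, predictors = "x"), "no events")
  d2 <- data.frame(x = rep(1, 50), ulcer_2yr = rbinom(50, 1, 0.3))
  expect_error(fit_logistic(d2, predictors = "x"), "`x` is constant")
  # complete separation: predictor perfectly splits the outcome
  d3 <- data.frame(x = rep(c(0, 1), each = 30),
                   ulcer_2yr = rep(c(0, 1), each = 30))
  expect_error(fit_logistic(d3, predictors = "x"), "separation.*x")
})

test_that("Wald intervals cover the generating coefficients about 95% of the time", {
  set.seed(314)
  truth <- c(1.11, 0.70, 1.95)
  intercept <- logit(0.022)
  reps <- 200
  covered <- matrix(FALSE, reps, 3)
  for (r in seq_len(reps)) {
    d <- sim_logistic_cohort(8255, intercept, truth)
    fit <- fit_logistic(d)
    se <- sqrt(diag(fit$vcov))[-1]
    lo <- fit$coefficients - 1.96 * se
    hi <- fit$coefficients + 1.96 * se
    covered[r, ] <- truth >= lo & truth <= hi
  }
  for (j in 1:3) {
    expect_gte(mean(covered[, j]), 0.90)
    expect_lte(mean(covered[, j]), 0.99)
  }
})

test_that("bootstrap shrinkage is near 1 at development scale and deterministic", {
  d <- sim_logistic_cohort(8255, logit(0.022), c(1.11, 0.70, 1.95))
  fit <- fit_logistic(d)
  sh <- shrinkage_factor(fit, d, n_bootstrap = 200, seed = 10)
  expect_gte(sh$s, 0.95)
  expect_lte(sh$s, 1.02)
  expect_gt(sh$s_heuristic, 0.9)
  sh2 <- shrinkage_factor(fit, d, n_bootstrap = 200, seed = 10)
  expect_identical(sh$s, sh2$s)
})

test_that("shrinkage flags small overfitted models and approaches 1 with n", {
  set.seed(5150)
  # n = 60, 10 events, 8 noise predictors: substantial optimism
  small <- as.data.frame(matrix(rbinom(60 * 8, 1, 0.5), 60, 8))
  names(small) <- paste0("z", 1:8)
  small$ulcer_2yr <- sample(rep(c(1L, 0L), c(10, 50)))
  fit_small <- fit_logistic(small, predictors = paste0("z", 1:8))
  s_small <- shrinkage_factor(fit_small, small, n_bootstrap = 100, seed = 2)
  expect_lt(s_small$s, 0.9)

  s_at <- vapply(c(200, 2000, 20000), function(n) {
    d <- sim_logistic_cohort(n, logit(0.05), c(1.11, 0.70, 1.95))
    f <- fit_logistic(d)
    shrinkage_factor(f, d, n_bootstrap = 100, seed = 3)$s
  }, numeric(1))
  expect_true(all(diff(abs(s_at - 1)) < 0))  # optimism shrinks with n
  expect_gt(s_at[3], 0.98)
})

test_that("coefficients convert to the published integer weights", {
  expect_equal(unname(convert_to_cpr(c(m = 1.11, p = 0.70, h = 1.95))),
               c(1L, 1L, 2L))
  expect_equal(unname(convert_to_cpr(c(m = 1.0, p = 1.0, h = 2.0))),
               c(1L, 1L, 2L))
  expect_warning(w <- convert_to_cpr(c(m = 0.49, p = 1.51, h = 2.5)),
                 "weight 0")
  expect_equal(unname(w), c(0L, 2L, 3L))  # ties round away from zero
  expect_error(convert_to_cpr(c(m = -0.2, p = 1, h = 2)), "positive")
})

test_that("scores enumerate correctly over all predictor combinations", {
  w <- c(mono_insensate = 1L, pulses_absent = 1L, history = 2L)
  combos <- expand.grid(mono_insensate = 0:1, pulses_absent = 0:1,
                        history = 0:1)
  expect_setequal(cpr_score(combos, w), c(0L, 1L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_equal(cpr_score(data.frame(mono_insensate = 1, pulses_absent = 0,
                                    history = 1), w), 3L)
  expect_error(cpr_score(data.frame(mono_insensate = NA, pulses_absent = 0,
                                    history = 1), w), "complete cases")
})

test_that("score model recovers its generating parameters (single study)", {
  set.seed(2024)
  alpha <- logit(0.024)
  gamma <- log(2.57)
  reps <- 200
  cover_a <- cover_g <- logical(reps)
  for (r in seq_len(reps)) {
    reg <- simulate_score_register(8255, alpha, gamma)
    sm <- fit_score_model(reg$score, reg$ulcer_2yr)
    se <- sqrt(diag(sm$vcov))
    cover_a[r] <- abs(sm$alpha - alpha) <= 1.96 * se[1]
    cover_g[r] <- abs(sm$gamma - gamma) <= 1.96 * se[2]
    expect_equal(sm$sigma_u, 0)
  }
  expect_gte(mean(cover_a), 0.90)
  expect_gte(mean(cover_g), 0.90)
})

test_that("between-study intercept SD is recovered from distinct study baselines", {
  set.seed(7)
  offsets <- c(-0.45, -0.15, 0.15, 0.45)
  alpha <- logit(0.05)
  gamma <- log(2.5)
  dat <- do.call(rbind, lapply(1:4, function(j) {
    reg <- simulate_score_register(4000, alpha + offsets[j], gamma)
    reg$study <- paste0("s", j)
    reg
  }))
  sm <- fit_score_model(dat$score, dat$ulcer_2yr, study = dat$study)
  truth_sd <- sqrt(mean(offsets^2))
  expect_lt(abs(sm$sigma_u - truth_sd) / truth_sd, 0.5)
  expect_lt(abs(sm$gamma - gamma), 0.1)

  # truth sigma_u = 0: estimate collapses to the boundary
  dat0 <- do.call(rbind, lapply(1:4, function(j) {
    reg <- simulate_score_register(2000, alpha, gamma)
    reg$study <- paste0("s", j)
    reg
  }))
  sm0 <- fit_score_model(dat0$score, dat0$ulcer_2yr, study = dat0$study)
  expect_lt(sm0$sigma_u, 0.1)
})

test_that("marginalization is exact at sigma_u = 0 and matches Monte Carlo otherwise", {
  sm0 <- score_model(alpha = logit(0.024), gamma = log(2.57), sigma_u = 0)
  p <- population_average_risk(sm0, 0:4)$probability
  expect_equal(p, inv_logit(logit(0.024) + log(2.57) * 0:4))

  # symmetry: eta = 0 marginalizes to exactly 1/2 for any sigma_u
  for (s in c(0, 0.5, 1, 2)) {
    sm <- score_model(alpha = 0, gamma = 0, sigma_u = s)
    expect_equal(population_average_risk(sm, 1)$probability, 0.5,
                 tolerance = 1e-10)
  }

  # Monte-Carlo oracle at sigma_u = 1 (agreement to 3 decimals)
  set.seed(123)
  for (alpha in c(logit(0.024), -1, 0.7)) {
    mc <- mean(plogis(alpha + rnorm(1e6)))
    sm <- score_model(alpha = alpha, gamma = 0.5, sigma_u = 1)
    expect_lt(abs(population_average_risk(sm, 0)$probability - mc), 5e-4)
  }

  # quadrature and analytic attenuation agree closely across the score
  # range: within 0.005 up to sigma_u = 0.6 and 0.007 at sigma_u = 1
  for (s in c(0.3, 0.6)) {
    sm <- score_model(alpha = logit(0.024), gamma = log(2.57), sigma_u = s)
    pq <- population_average_risk(sm, 0:4)$probability
    pa <- population_average_risk(sm, 0:4, method = "attenuation")$probability
    expect_lt(max(abs(pq - pa)), 0.005)
  }
  sm1 <- score_model(alpha = logit(0.024), gamma = log(2.57), sigma_u = 1)
  expect_lt(max(abs(
    population_average_risk(sm1, 0:4)$probability -
      population_average_risk(sm1, 0:4, method = "attenuation")$probability)),
    0.007)

  expect_error(population_average_risk(sm0, 7), "out of range")
})

test_that("heterogeneity attenuates risks toward one half (Jensen)", {
  eta <- logit(c(0.024, 0.14, 0.8))
  p0 <- inv_logit(eta)
  sm <- function(e, s) population_average_risk(
    score_model(alpha = e, gamma = 0, sigma_u = s), 0)$probability
  for (i in seq_along(eta)) {
    pm <- sm(eta[i], 0.8)
    expect_true(abs(pm - 0.5) < abs(p0[i] - 0.5))
  }
})

test_that("the risk table is strictly increasing in score for positive gamma", {
  reg <- simulate_score_register(5000, logit(0.024), log(2.57), seed = 6)
  sm <- fit_score_model(reg$score, reg$ulcer_2yr)
  tab <- build_risk_table(sm, reg$score)
  expect_equal(tab$score, 0:4)
  expect_equal(sum(tab$n), 5000)
  expect_true(all(diff(tab$probability) > 0))
  expect_true(all(tab$probability > 0 & tab$probability < 1))
  expect_true(all(tab$lower < tab$probability & tab$probability < tab$upper))

  flat <- build_risk_table(score_model(logit(0.05), 0), reg$score)
  expect_equal(unique(flat$probability), inv_logit(logit(0.05)))
})

test_that("end-to-end development recovers the generating rule", {
  suite <- harmonize_records(simulate_development_suite(
    seed = 1, outcome_model = "logistic", study_intercept_sd = 0.3))
  rule <- develop_cpr(suite, n_bootstrap = 0)
  expect_equal(unname(rule$weights), c(1L, 1L, 2L))
  expect_equal(rule$score_range, c(0L, 4L))
  expect_true(all(diff(rule$risk_table$probability) > 0))
  expect_lt(abs(rule$heterogeneity_sd - 0.3), 0.25)

  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(rule, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$weights$history, 2L)
  expect_length(back$risk_table, 5)
})
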