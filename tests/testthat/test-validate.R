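test_that("C-statistic equals brute-force pair enumeration", {
  expect_equal(c_statistic(c(1, 2, 2, 3), c(0, 0, 1, 1))$c, 3.5 / 4)

  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    scores <- sample(0:6, n, replace = TRUE)
    outcomes <- rbinom(n, 1, 0.4)
    if (sum(outcomes) %in% c(0, n)) next
    expect_equal(c_statistic(scores, outcomes)$c,
                 brute_force_c(scores, outcomes),
                 tolerance = 1e-12)
  }
})

test_that("C-statistic hits its boundary and chance anchors", {
  # perfect separation
  expect_equal(c_statistic(c(1, 1, 9, 9), c(0, 0, 1, 1))$c, 1)
  # chance under permutation on a large register
  reg <- simulate_score_register(20000, logit(0.024), log(2.57), seed = 4)
  perm <- ulcerscore:::with_seed(99, sample(reg$ulcer_2yr))
  cs <- c_statistic(reg$score, perm)
  expect_lt(abs(cs$c - 0.5), 0.02)
  # errors on degenerate outcomes
  expect_error(c_statistic(1:4, c(1, 1, 1, 1)), "events")
  expect_error(c_statistic(1:4, c(0, 0, 0, 0)), "events")
})

test_that("C-statistic is invariant under strictly increasing transforms", {
  set.seed(23)
  scores <- rnorm(500)
  outcomes <- rbinom(500, 1, plogis(scores))
  base <- c_statistic(scores, outcomes)$c
  expect_equal(c_statistic(exp(scores), outcomes)$c, base)
  expect_equal(c_statistic(rank(scores), outcomes)$c, base)
  expect_equal(c_statistic(3 * scores - 7, outcomes)$c, base)
})

test_that("DeLong interval matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- sample(0:4, 600, replace = TRUE)
  outcomes <- rbinom(600, 1, plogis(-2 + scores))
  cs <- c_statistic(scores, outcomes)
  ref <- pROC::ci.auc(pROC::roc(outcomes, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(cs$c, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(cs$lower, as.numeric(ref[1]), tolerance = 1e-6)
  expect_equal(cs$upper, as.numeric(ref[3]), tolerance = 1e-6)
})

test_that("calibration metrics recover slope 1 / ITL 0 on self-simulated data", {
  reg <- simulate_score_register(20000, logit(0.024), log(2.57), seed = 12)
  cal <- calibration_metrics(reg$lp, reg$ulcer_2yr)
  expect_lt(abs(cal$slope["estimate"] - 1), 0.1)
  expect_lt(abs(cal$itl["estimate"]), 0.1)
  expect_lt(cal$slope["lower"], cal$slope["estimate"])
  expect_gt(cal$slope["upper"], cal$slope["estimate"])
})

test_that("calibration detects overconfident predictors and average-risk shifts", {
  set.seed(41)
  n <- 20000
  x <- rnorm(n)
  true_lp <- -2 + x
  y <- rbinom(n, 1, plogis(true_lp))
  # supplied lp twice the true logit: slope should halve
  cal <- calibration_metrics(2 * true_lp, y)
  expect_lt(abs(cal$slope["estimate"] - 0.5), 0.05)
  # outcomes generated 0.5 log-odds above the validated predictor
  y_shift <- rbinom(n, 1, plogis(true_lp + 0.5))
  cal2 <- calibration_metrics(true_lp, y_shift)
  expect_lt(abs(cal2$itl["estimate"] - 0.5), 0.1)
  expect_error(calibration_metrics(rep(1.5, 100), rbinom(100, 1, 0.3)),
               "constant")
})

test_that("slope and ITL intervals achieve near-nominal coverage", {
  set.seed(2718)
  reps <- 200
  cover_b <- cover_a <- logical(reps)
  for (r in seq_len(reps)) {
    reg <- simulate_score_register(3324, logit(0.024), log(2.57))
    cal <- calibration_metrics(reg$lp, reg$ulcer_2yr)
    cover_b[r] <- cal$slope["lower"] <= 1 && 1 <= cal$slope["upper"]
    cover_a[r] <- cal$itl["lower"] <= 0 && 0 <= cal$itl["upper"]
  }
  expect_gte(mean(cover_b), 0.90)
  expect_gte(mean(cover_a), 0.90)
})

test_that("grouped calibration rows count events with exact binomial intervals", {
  tab <- data.frame(score = 0:4,
                    probability = plogis(logit(0.024) + log(2.57) * 0:4))
  grp <- calibration_groups(rep(0L, 100), c(rep(1, 2), rep(0, 98))[1:100],
                            tab)
  expect_equal(nrow(grp), 1)
  expect_equal(grp$n, 100)
  expect_equal(grp$observed, 0.02)
  ref <- binom.test(2, 100)$conf.int
  expect_equal(c(grp$lower, grp$upper), as.numeric(ref))

  # absent score level omitted with a message
  scores <- c(rep(0L, 50), rep(1L, 30), rep(2L, 20))
  outcomes <- rbinom(100, 1, 0.1)
  outcomes[1] <- 1
  expect_message(grp2 <- calibration_groups(scores, outcomes, tab),
                 "omitted")
  expect_equal(grp2$score, 0:2)
  expect_equal(sum(grp2$n), 100)
})

test_that("self-simulated register is well calibrated group by group", {
  sm <- score_model(logit(0.024), log(2.57))
  tab <- build_risk_table(sm, 0:4)
  reg <- simulate_score_register(3324, logit(0.024), log(2.57), seed = 19)
  grp <- suppressMessages(
    calibration_groups(reg$score, reg$ulcer_2yr, tab))
  inside <- grp$predicted >= grp$lower & grp$predicted <= grp$upper
  expect_gte(sum(inside), nrow(grp) - 1)
})

test_that("ROC points anchor correctly and integrate to the C-statistic", {
  # perfect separation passes through (0, 1)
  pts <- roc_points(c(1, 1, 9, 9), c(0, 0, 1, 1))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))

  # worked instance and general identity with the rank C-statistic
  pts2 <- roc_points(c(1, 2, 2, 3), c(0, 0, 1, 1))
  expect_equal(ulcerscore:::trapezoid_auc(pts2), 0.875, tolerance = 1e-12)

  set.seed(53)
  for (i in 1:50) {
    n <- sample(5:150, 1)
    scores <- sample(0:4, n, replace = TRUE)
    outcomes <- rbinom(n, 1, 0.3)
    if (sum(outcomes) %in% c(0, n)) next
    pts <- roc_points(scores, outcomes)
    expect_equal(ulcerscore:::trapezoid_auc(pts),
                 c_statistic(scores, outcomes)$c, tolerance = 1e-12)
    expect_equal(pts[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
  }

  # binary score: exactly 3 points
  expect_equal(nrow(roc_points(c(0, 0, 1, 1), c(0, 1, 0, 1))), 3)
})

test_that("validate_cpr refuses raw scores and reports coherent metrics", {
  reg <- simulate_score_register(3324, logit(0.024), log(2.57), seed = 29)
  expect_error(validate_cpr(reg$score, reg$ulcer_2yr, model = reg$score),
               "score_model")
  sm <- score_model(logit(0.024), log(2.57))
  tab <- build_risk_table(sm, reg$score)
  rep_ <- validate_cpr(reg$score, reg$ulcer_2yr, sm, risk_table = tab)
  expect_s3_class(rep_, "validation_report")
  expect_equal(rep_$n_used, 3324)
  expect_equal(sum(rep_$groups$n), rep_$n_used)
  expect_true(rep_$c_statistic$c >= 0 && rep_$c_statistic$c <= 1)
  expect_lt(abs(rep_$calibration_slope["estimate"] - 1), 0.25)

  path <- withr::local_tempfile(fileext = ".json")
  write_validation_json(rep_, path)
  expect_equal(jsonlite::read_json(path)$n_used, 3324)
})

test_that("score and full-model validation discriminate almost identically", {
  spec <- validation_cohort_spec(outcome_model = "logistic")
  val <- harmonize_records(simulate_cohort(spec, seed = 43))
  w <- c(mono_insensate = 1L, pulses_absent = 1L, history = 2L)
  scores <- cpr_score(val, w)
  lp_full <- logit(0.022) + as.matrix(val[names(w)]) %*% c(1.11, 0.70, 1.95)
  c_score <- c_statistic(scores, val$ulcer_2yr)$c
  c_full <- c_statistic(drop(lp_full), val$ulcer_2yr)$c
  expect_lt(abs(c_score - c_full), 0.02)
})
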