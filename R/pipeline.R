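#' Run the full development-validation-decision pipeline
#'
#' Executes the stages end to end — obtain individual-participant data
#' (simulated from a scenario, or read from CSV), harmonize and
#' complete-case filter, develop the rule (prognostic model, shrinkage
#' check, score conversion, score model, risk table), validate it on the
#' validation data, and run the decision-curve analysis with a referral
#' threshold recommendation — writing all JSON/CSV/PNG artifacts, a
#' human-readable report, and a machine-readable run manifest to `out_dir`.
#'
#' The configuration is a YAML file (or equivalent list) with keys:
#' \describe{
#'   \item{simulate}{mapping with `outcome_model` (`"logistic"` is required
#'     for rule development), `study_intercept_sd`, and optional
#'     `intercept` / `coefficients`; the built-in development and
#'     validation cohort specifications are used. Alternatively:}
#'   \item{development_csv / validation_csv}{paths of cohort CSVs in either
#'     dialect of [read_cohort_csv()].}
#'   \item{n_bootstrap}{bootstrap resamples for the shrinkage check
#'     (default 200; 0 skips).}
#'   \item{thresholds}{mapping `lo`/`hi`/`step` for the decision grid.}
#' }
#' Any stage failure is reported as an error tagged with the stage name.
#'
#' @param config Path to a YAML configuration file, or a list with the same
#'   structure.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer root seed; every source of randomness in the run
#'   derives from it and it is recorded in the manifest.
#' @param verbose Print progress messages.
#' @return Invisibly, a list with the fitted `rule`, the
#'   `validation_report`, the `decision_curve`, the `recommendation`, and
#'   the `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  n_bootstrap <- config$n_bootstrap %||% 200
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 4))

  # ---- stage: data -----------------------------------------------------
  dat <- if (!is.null(config$development_csv)) {
    NULL  # CSV inputs are read (and coded) in the harmonize stage
  } else {
    stage("simulate", {
      sim <- config$simulate %||% list()
      om <- sim$outcome_model %||% "logistic"
      args <- list(outcome_model = om)
      if (om == "logistic") {
        args$study_intercept_sd <- sim$study_intercept_sd %||% 0.3
        if (!is.null(sim$intercept)) args$intercept <- sim$intercept
        if (!is.null(sim$coefficients)) args$coefficients <- sim$coefficients
      }
      dev <- do.call(simulate_development_suite, c(list(seed = seeds[1]), args))
      val_args <- args
      val_args$study_intercept_sd <- 0
      val <- simulate_cohort(do.call(validation_cohort_spec, val_args),
                             seed = seeds[2])
      list(dev = dev, val = val)
    })
  }

  # ---- stage: harmonize ------------------------------------------------
  cc <- stage("harmonize", {
    if (is.null(dat)) {
      dat <- list(
        dev = do.call(rbind, lapply(config$development_csv, read_cohort_csv)),
        val = read_cohort_csv(config$validation_csv))
    }
    dev <- complete_case_filter(harmonize_records(dat$dev))
    val <- complete_case_filter(harmonize_records(dat$val))
    list(dev = dev, val = val)
  })
  say("harmonize: retained %d / %d development, %d / %d validation",
      cc$dev$report$n_retained, cc$dev$report$n_input,
      cc$val$report$n_retained, cc$val$report$n_input)

  # ---- stage: develop --------------------------------------------------
  rule <- stage("develop", {
    develop_cpr(cc$dev$retained, n_bootstrap = n_bootstrap, seed = seeds[3])
  })
  say("develop: weights (%s), per-point OR %.2f",
      paste(rule$weights, collapse = ", "), exp(rule$score_model$gamma))

  # ---- stage: validate -------------------------------------------------
  report <- stage("validate", {
    val <- cc$val$retained
    scores <- cpr_score(val, rule$weights)
    validate_cpr(scores, val$ulcer_2yr, rule)
  })

  # ---- stage: decide ---------------------------------------------------
  decide <- stage("decide", {
    val <- cc$val$retained
    scores <- cpr_score(val, rule$weights)
    risks <- rule$risk_table$probability[match(scores, rule$risk_table$score)]
    tg <- config$thresholds
    grid <- if (is.null(tg)) seq(0.005, 0.30, by = 0.005) else {
      seq(tg$lo, tg$hi, by = tg$step)
    }
    curve <- decision_curve(val$ulcer_2yr, risks, thresholds = grid)
    rec <- recommend_threshold(curve, rule$risk_table)
    list(curve = curve, recommendation = rec, scores = scores)
  })

  # ---- stage: report ---------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("ulcerscore")),
    root_seed = seed,
    stage_seeds = as.list(seeds),
    n_bootstrap = n_bootstrap,
    inputs = if (!is.null(config$development_csv)) {
      list(development_csv = config$development_csv,
           validation_csv = config$validation_csv)
    } else list(simulated = TRUE),
    counts = list(
      development = cc$dev$report[c("n_input", "n_retained", "n_excluded")],
      validation = cc$val$report[c("n_input", "n_retained", "n_excluded")]
    )
  )

  stage("report", {
    p <- function(f) file.path(out_dir, f)
    write_model_json(rule, p("cpr_rule.json"))
    write_risk_table_csv(rule$risk_table, p("risk_table.csv"))
    write_validation_json(report, p("validation.json"))
    if (!is.null(report$groups)) {
      utils::write.csv(report$groups, p("calibration_groups.csv"),
                       row.names = FALSE)
    }
    val <- cc$val$retained
    utils::write.csv(roc_points(decide$scores, val$ulcer_2yr),
                     p("roc_points.csv"), row.names = FALSE)
    write_decision_curve_csv(decide$curve, p("decision_curve.csv"))
    plot_calibration(report, file = p("calibration.png"))
    plot(decide$curve, file = p("decision_curve.png"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(pipeline_report_text(rule, report, decide$recommendation,
                                    manifest),
               p("report.txt"))
  })
  say("artifacts written to %s", out_dir)

  invisible(list(rule = rule, validation = report, curve = decide$curve,
                 recommendation = decide$recommendation, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_report_text <- function(rule, report, rec, manifest) {
  fmt_tab <- utils::capture.output(
    print(rule$risk_table, row.names = FALSE, digits = 3))
  c("2-year diabetic foot ulcer clinical prediction rule: run report",
    strrep("=", 64),
    "",
    sprintf("Development: %d records in, %d complete cases used",
            manifest$counts$development$n_input,
            manifest$counts$development$n_retained),
    sprintf("Validation:  %d records in, %d complete cases used",
            manifest$counts$validation$n_input,
            manifest$counts$validation$n_retained),
    "",
    "Score weights:",
    sprintf("  %-18s +%d", names(rule$weights), rule$weights),
    "",
    "Population-average risk by score:",
    paste(" ", fmt_tab),
    "",
    sprintf("Validation C-statistic: %.3f (%.3f to %.3f)",
            report$c_statistic$c, report$c_statistic$lower,
            report$c_statistic$upper),
    sprintf("Calibration slope:      %.3f (%.3f to %.3f)",
            report$calibration_slope["estimate"],
            report$calibration_slope["lower"],
            report$calibration_slope["upper"]),
    sprintf("Calibration-in-large:   %.3f (%.3f to %.3f)",
            report$calibration_itl["estimate"],
            report$calibration_itl["lower"],
            report$calibration_itl["upper"]),
    "",
    if (isTRUE(rec$recommended)) {
      sprintf("Recommendation: refer at score >= %d (2-year risk >= %.1f%%)",
              rec$score, 100 * rec$risk)
    } else {
      "Recommendation: no score threshold dominates treat-all/treat-none"
    })
}
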