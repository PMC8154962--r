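#' Code monofilament insensitivity from per-site results
#'
#' A participant is coded insensate (1) if the 10 g monofilament was not
#' felt at any tested site, and 0 if it was felt at all sites. Studies use
#' varying numbers of plantar sites, so any positive number of entries is
#' accepted.
#'
#' With some sites missing, the permissive default codes 0 whenever at least
#' one site was felt and none was insensate, on the reading that the rule
#' keys on insensitivity anywhere; `strict = TRUE` instead returns missing
#' unless every site was observed (or some site was insensate).
#'
#' @param site_results Character vector with entries `"felt"`, `"not_felt"`,
#'   or `NA`.
#' @param strict Logical; see Details.
#' @return 1, 0, or `NA_integer_`.
#' @export
#' @examples
#' code_monofilament(c("felt", "not_felt", "felt"))  # 1
#' code_monofilament(c(NA, "felt"))                  # 0 (permissive)
#' code_monofilament(c(NA, "felt"), strict = TRUE)   # NA
code_monofilament <- function(site_results, strict = FALSE) {
  if (length(site_results) == 0L) {
    stop("`site_results` must contain at least one site", call. = FALSE)
  }
  bad <- !site_results %in% c("felt", "not_felt") & !is.na(site_results)
  if (any(bad)) {
    stop(sprintf("invalid site result(s): %s",
                 paste(unique(site_results[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(site_results == "not_felt", na.rm = TRUE)) return(1L)
  if (all(is.na(site_results))) return(NA_integer_)
  if (strict && anyNA(site_results)) return(NA_integer_)
  0L
}

#' Code absent pedal pulses from the four pulse examinations
#'
#' Coded 1 if any of the four pedal pulses (dorsalis pedis and posterior
#' tibial, each foot) is absent, 0 if all four are present, and missing if
#' no pulse is absent but at least one examination is missing. Note the
#' asymmetry with [code_monofilament()]: a single unexamined pulse leaves a
#' 0 unconfirmable, because 0 requires all four present.
#'
#' @param pulse_results Character vector of exactly four entries
#'   `"present"`, `"absent"`, or `NA`.
#' @return 1, 0, or `NA_integer_`.
#' @export
#' @examples
#' code_pulses(c("present", "present", "present", "absent"))  # 1
#' code_pulses(c("present", NA, "present", "present"))        # NA
code_pulses <- function(pulse_results) {
  if (length(pulse_results) != 4L) {
    stop(sprintf("`pulse_results` must have exactly 4 entries (got %d)",
                 length(pulse_results)), call. = FALSE)
  }
  bad <- !pulse_results %in% c("present", "absent") & !is.na(pulse_results)
  if (any(bad)) {
    stop(sprintf("invalid pulse result(s): %s",
                 paste(unique(pulse_results[bad]), collapse = ", ")),
         call. = FALSE)
  }
  if (any(pulse_results == "absent", na.rm = TRUE)) return(1L)
  if (anyNA(pulse_results)) return(NA_integer_)
  0L
}

#' Code history of previous ulcer or amputation
#'
#' Three-valued logical OR: 1 if either component is 1, 0 if both are 0,
#' missing otherwise (a missing component could conceal a 1).
#'
#' @param prior_ulcer,prior_amputation 0, 1, or `NA`. Vectorized.
#' @return Integer vector of 1, 0, or `NA`.
#' @export
#' @examples
#' code_history(0, 1)   # 1
#' code_history(NA, 0)  # NA
#' code_history(NA, 1)  # 1
code_history <- function(prior_ulcer, prior_amputation) {
  ok <- function(x) all(x %in% c(0, 1) | is.na(x))
  if (!ok(prior_ulcer) || !ok(prior_amputation)) {
    stop("history components must be 0, 1, or NA", call. = FALSE)
  }
  out <- ifelse(prior_ulcer %in% 1 | prior_amputation %in% 1, 1L,
                ifelse(!is.na(prior_ulcer) & !is.na(prior_amputation), 0L,
                       NA_integer_))
  as.integer(out)
}

#' Harmonize raw cohort records into coded analysis records
#'
#' Adds the derived `history` column (three-valued OR of `prior_ulcer` and
#' `prior_amputation`) to records that already carry coded
#' `mono_insensate` / `pulses_absent` columns.
#'
#' @param records Data frame with columns `mono_insensate`, `pulses_absent`,
#'   `prior_ulcer`, `prior_amputation`, `ulcer_2yr` and optionally
#'   `study_label`.
#' @return The input with a `history` column appended.
#' @export
harmonize_records <- function(records) {
  needed <- c("mono_insensate", "pulses_absent", "prior_ulcer",
              "prior_amputation", "ulcer_2yr")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop(sprintf("records lack column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records$history <- code_history(records$prior_ulcer, records$prior_amputation)
  records
}

#' Read a cohort CSV in either the coded or the raw dialect
#'
#' Two dialects are supported. The *coded* dialect carries the analysis
#' columns directly (`mono_insensate`, `pulses_absent`, `prior_ulcer`,
#' `prior_amputation`, `ulcer_2yr`). The *raw* dialect carries per-site
#' monofilament columns `mono_site_1 ... mono_site_k` (values `felt` /
#' `not_felt` / empty) and four pulse columns `pulse_dp_left`,
#' `pulse_pt_left`, `pulse_dp_right`, `pulse_pt_right` (values `present` /
#' `absent` / empty), which are coded per participant with
#' [code_monofilament()] and [code_pulses()]. Empty fields are missing.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (detect from the header), `"coded"`, or `"raw"`.
#' @param strict_monofilament Passed to [code_monofilament()].
#' @return A harmonized data frame (see [harmonize_records()]).
#' @export
read_cohort_csv <- function(path, dialect = c("auto", "coded", "raw"),
                            strict_monofilament = FALSE) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (dialect == "auto") {
    dialect <- if ("mono_insensate" %in% names(df)) "coded" else "raw"
  }
  if (dialect == "raw") {
    mono_cols <- grep("^mono_site_[0-9]+$", names(df), value = TRUE)
    pulse_cols <- c("pulse_dp_left", "pulse_pt_left",
                    "pulse_dp_right", "pulse_pt_right")
    if (!length(mono_cols)) {
      stop("raw dialect requires mono_site_* columns", call. = FALSE)
    }
    if (!all(pulse_cols %in% names(df))) {
      stop("raw dialect requires the four pulse_* columns", call. = FALSE)
    }
    df$mono_insensate <- vapply(seq_len(nrow(df)), function(i) {
      code_monofilament(as.character(df[i, mono_cols]),
                        strict = strict_monofilament)
    }, integer(1))
    df$pulses_absent <- vapply(seq_len(nrow(df)), function(i) {
      code_pulses(as.character(df[i, pulse_cols]))
    }, integer(1))
    df <- df[, setdiff(names(df), c(mono_cols, pulse_cols))]
  }
  harmonize_records(df)
}

#' Complete-case filter over the three predictors and the outcome
#'
#' Retains records with `mono_insensate`, `pulses_absent`, `history`, and
#' `ulcer_2yr` all observed, without altering any field, and reports what
#' was excluded. No imputation is performed anywhere in the package.
#'
#' @param records Harmonized data frame (see [harmonize_records()]).
#' @return A list with elements `retained` (data frame), `excluded`
#'   (data frame), and `report`: per-field missing counts, number excluded,
#'   and the retention fraction.
#' @export
#' @examples
#' suite <- simulate_development_suite(seed = 1, missing_rate = 0.01)
#' cc <- complete_case_filter(harmonize_records(suite))
#' cc$report$retention
complete_case_filter <- function(records) {
  if (!"history" %in% names(records)) {
    records <- harmonize_records(records)
  }
  fields <- c("mono_insensate", "pulses_absent", "history", "ulcer_2yr")
  n <- nrow(records)
  if (n == 0L) {
    return(list(retained = records, excluded = records,
                report = list(n_input = 0L, n_retained = 0L, n_excluded = 0L,
                              retention = NA_real_,
                              missing_by_field = stats::setNames(
                                rep(0L, length(fields)), fields))))
  }
  miss <- vapply(records[fields], function(x) is.na(x), logical(n))
  if (n == 1L) miss <- matrix(miss, nrow = 1, dimnames = list(NULL, fields))
  keep <- rowSums(miss) == 0
  list(
    retained = records[keep, , drop = FALSE],
    excluded = records[!keep, , drop = FALSE],
    report = list(
      n_input = n,
      n_retained = sum(keep),
      n_excluded = sum(!keep),
      retention = sum(keep) / n,
      missing_by_field = colSums(miss)
    )
  )
}
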