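# Patient-level domain model: presentation records, eligibility, and the
# three-component disposition score in its three variants.

#' Disposition score variants
#'
#' The score awards one point for altered mental status, one point for
#' impaired mobility, and one point for a deranged respiratory measurement.
#' Three variants differ in which assessments feed those components:
#'
#' * `"sat"` — subjective mental status (alert/attentive/calm/coherent) and
#'   oxygen saturation < 94\% (the default score, KHDS);
#' * `"resp"` — subjective mental status and respiratory rate > 23 breaths
#'   per minute (KHDSr);
#' * `"months"` — months-backwards test for mental status and oxygen
#'   saturation < 94\% (KHDSm).
#'
#' @format Character vector of the three variant codes.
#' @export
khds_variants <- c("sat", "resp", "months")

#' Recognised gait categories, from least to most impaired
#'
#' Only `"stable_independent"` counts as unimpaired mobility; the four
#' impaired categories are retained so richer source data survives I/O and
#' are collapsed to a binary point at scoring time.
#'
#' @format Character vector of five gait codes.
#' @export
gait_levels <- c("stable_independent", "unsteady", "uses_aid",
                 "needs_help", "bedridden")

match_variant <- function(variant) {
  match.arg(variant, khds_variants)
}

stop_khds <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "khds_error")))
}

#' Mobility component of the disposition score
#'
#' One point for any lack of a stable independent gait: patients who are
#' unsteady, use a walking aid, need help to walk, or are bedridden all
#' score the point.
#'
#' @param gait Character vector of gait categories (see [gait_levels]).
#' @return Integer vector of 0/1 points; `NA` where `gait` is `NA`.
#' @export
#' @examples
#' mobility_point(c("stable_independent", "uses_aid", "bedridden"))
mobility_point <- function(gait) {
  bad <- !is.na(gait) & !(gait %in% gait_levels)
  if (any(bad)) {
    stop_khds(sprintf("unknown gait category: %s",
                      paste(unique(gait[bad]), collapse = ", ")),
              "khds_validation_error")
  }
  ifelse(is.na(gait), NA_integer_,
         as.integer(gait != "stable_independent"))
}

#' Mental-status component of the disposition score
#'
#' Subjective variants (`"sat"`, `"resp"`): a patient has normal mental
#' status only if alert, attentive, calm, and coherent — failing any one
#' of the four scores the point. The `"months"` variant instead uses the
#' objective months-backwards test (reciting the months in reverse from
#' December to July); failure — including inability to attempt the test —
#' scores the point.
#'
#' @param records Cohort data frame (see [read_cohort] for the schema).
#' @param variant One of [khds_variants].
#' @param on_missing `"na"` (default) returns `NA` where the required
#'   assessment is missing; `"error"` raises a condition of class
#'   `khds_missing_component`.
#' @return Integer vector of 0/1 points, `NA` for unassessed records.
#' @export
mental_point <- function(records, variant = "sat",
                         on_missing = c("na", "error")) {
  variant <- match_variant(variant)
  on_missing <- match.arg(on_missing)
  if (variant == "months") {
    pt <- ifelse(is.na(records$months_backwards_pass), NA_integer_,
                 as.integer(!records$months_backwards_pass))
    missing_field <- "months_backwards_pass"
  } else {
    flags <- cbind(records$alert, records$attentive,
                   records$calm, records$coherent)
    normal <- rowSums(flags) == 4L   # NA if any flag NA
    pt <- as.integer(!normal)
    missing_field <- "alert/attentive/calm/coherent"
  }
  if (on_missing == "error" && anyNA(pt)) {
    stop_khds(sprintf("missing mental-status component (%s) for %d record(s)",
                      missing_field, sum(is.na(pt))),
              "khds_missing_component")
  }
  pt
}

#' Respiratory component of the disposition score
#'
#' Variants `"sat"` and `"months"` read oxygen saturation and award the
#' point for SpO2 strictly below 94\%; variant `"resp"` reads respiratory
#' rate and awards the point strictly above 23 breaths/min. The boundary
#' values (SpO2 = 94, rate = 23) do not score.
#'
#' @inheritParams mental_point
#' @return Integer vector of 0/1 points, `NA` for unmeasured records.
#' @export
respiratory_point <- function(records, variant = "sat",
                              on_missing = c("na", "error")) {
  variant <- match_variant(variant)
  on_missing <- match.arg(on_missing)
  if (variant == "resp") {
    pt <- ifelse(is.na(records$resp_rate), NA_integer_,
                 as.integer(records$resp_rate > 23))
    missing_field <- "resp_rate"
  } else {
    pt <- ifelse(is.na(records$spo2), NA_integer_,
                 as.integer(records$spo2 < 94))
    missing_field <- "spo2"
  }
  if (on_missing == "error" && anyNA(pt)) {
    stop_khds(sprintf("missing respiratory component (%s) for %d record(s)",
                      missing_field, sum(is.na(pt))),
              "khds_missing_component")
  }
  pt
}

#' Compute the disposition score
#'
#' Sums the mental-status, mobility, and respiratory components (each 0 or
#' 1) for every record, under the component definitions selected by
#' `variant`. Records missing any component required by the variant get
#' `NA` points and are excluded from that variant's analysis set
#' (complete-case per variant; nothing is imputed).
#'
#' @inheritParams mental_point
#' @return Data frame with one row per record: `variant`, `points` (0-3 or
#'   `NA`), and the three component columns `mental_point`,
#'   `mobility_point`, `respiratory_point`.
#' @export
#' @examples
#' coh <- generate_cohort(default_config(n = 5), seed = 1)
#' compute_khds(coh, "sat")
compute_khds <- function(records, variant = "sat",
                         on_missing = c("na", "error")) {
  variant <- match_variant(variant)
  on_missing <- match.arg(on_missing)
  mental <- mental_point(records, variant, on_missing)
  mobility <- mobility_point(records$gait)
  resp <- respiratory_point(records, variant, on_missing)
  data.frame(variant = variant,
             points = mental + mobility + resp,
             mental_point = mental,
             mobility_point = mobility,
             respiratory_point = resp)
}

#' Study eligibility: non-pregnant patients aged 12 years or older
#'
#' @param records Cohort data frame with `age` and `pregnant` columns.
#' @return Logical vector; `TRUE` for eligible records.
#' @export
is_eligible <- function(records) {
  records$age >= 12 & !records$pregnant
}

# ---- CSV round-trip I/O -----------------------------------------------------

cohort_columns <- c("patient_id", "age", "sex", "arrival", "pregnant",
                    "alert", "attentive", "calm", "coherent",
                    "months_backwards_pass", "gait", "spo2", "resp_rate",
                    "presentations", "admitted", "died_within_24h",
                    "died_in_hospital", "day_of_death")

cohort_logical_cols <- c("pregnant", "alert", "attentive", "calm", "coherent",
                         "months_backwards_pass", "admitted",
                         "died_within_24h", "died_in_hospital")

#' Validate a cohort data frame
#'
#' Checks column presence, types, vital-sign ranges (SpO2 in \[0, 100\],
#' respiratory rate in \[0, 120\]), enum levels, and the outcome-nesting
#' invariants (death within 24 h implies in-hospital death implies
#' admission; death within 24 h corresponds to day of death 0).
#'
#' @param records Data frame to validate.
#' @return Invisibly, `records`. Raises a `khds_validation_error` listing
#'   offending rows otherwise.
#' @export
validate_cohort <- function(records) {
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols)) {
    stop_khds(paste("missing cohort columns:",
                    paste(missing_cols, collapse = ", ")),
              "khds_validation_error")
  }
  problems <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%s (rows %s)", what,
        paste(utils::head(rows, 10), collapse = ", ")))
    }
  }
  flag(!is.na(records$spo2) & (records$spo2 < 0 | records$spo2 > 100),
       "spo2 outside [0, 100]")
  flag(!is.na(records$resp_rate) &
         (records$resp_rate < 0 | records$resp_rate > 120),
       "resp_rate outside [0, 120]")
  flag(!is.na(records$age) & records$age < 0, "negative age")
  flag(!records$sex %in% c("male", "female"), "sex not male/female")
  flag(!is.na(records$gait) & !records$gait %in% gait_levels,
       "unknown gait category")
  flag(records$died_within_24h & !records$died_in_hospital,
       "died_within_24h without died_in_hospital")
  flag(records$died_in_hospital & !records$admitted,
       "died_in_hospital without admitted")
  flag(records$died_within_24h & !is.na(records$day_of_death) &
         records$day_of_death != 0,
       "died_within_24h with day_of_death != 0")
  arrival_ok <- is.na(records$arrival) |
    !is.na(as.POSIXct(records$arrival, format = "%Y-%m-%dT%H:%M:%S",
                      tz = "UTC"))
  flag(!arrival_ok, "unparseable arrival timestamp (want ISO 8601)")
  if (length(problems)) {
    stop_khds(paste0("invalid cohort:\n  ",
                     paste(problems, collapse = "\n  ")),
              "khds_validation_error")
  }
  invisible(records)
}

#' Read a cohort CSV
#'
#' The canonical cohort format is a CSV with one row per presentation and
#' the documented column set (see Details). Empty cells encode missing
#' values; booleans are written `true`/`false`; `presentations` is a
#' semicolon-separated list of SATS presentation codes, where an empty cell
#' means the patient was never ranked and the pseudo-code `non_urgent`
#' means ranked with nothing urgent found.
#'
#' @details Columns: `patient_id`, `age`, `sex`, `arrival` (ISO 8601),
#'   `pregnant`, `alert`, `attentive`, `calm`, `coherent`,
#'   `months_backwards_pass`, `gait`, `spo2`, `resp_rate`,
#'   `presentations`, `admitted`, `died_within_24h`, `died_in_hospital`,
#'   `day_of_death`.
#'
#' @param path Path to the CSV file.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = "character",
                             na.strings = character())
  missing_cols <- setdiff(cohort_columns, names(records))
  if (length(missing_cols)) {
    stop_khds(paste("malformed header; missing columns:",
                    paste(missing_cols, collapse = ", ")),
              "khds_validation_error")
  }
  records <- records[cohort_columns]
  as_na <- function(x) ifelse(x == "", NA, x)
  records[] <- lapply(records, as_na)
  for (col in c("age", "day_of_death")) {
    records[[col]] <- as.integer(records[[col]])
  }
  for (col in c("spo2", "resp_rate")) {
    records[[col]] <- as.numeric(records[[col]])
  }
  for (col in cohort_logical_cols) {
    v <- records[[col]]
    bad <- !is.na(v) & !v %in% c("true", "false")
    if (any(bad)) {
      stop_khds(sprintf("column %s not true/false (rows %s)", col,
                        paste(utils::head(which(bad), 10), collapse = ", ")),
                "khds_validation_error")
    }
    records[[col]] <- v == "true"
  }
  validate_cohort(records)
  records
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort]: writing then reading yields identical records.
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  out <- records[cohort_columns]
  for (col in cohort_logical_cols) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "true", "false"))
  }
  out[] <- lapply(out, function(x) ifelse(is.na(x), "", as.character(x)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
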