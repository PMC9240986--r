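# South African Triage Scale (SATS) presentation taxonomy as observed in a
# low-resource emergency/outpatient setting, and per-patient urgency ranking.

#' SATS urgency levels, least to most urgent
#'
#' Ordinal taxonomy: non-urgent (rank 0) < urgent (1) < very urgent (2) <
#' emergent (3). A patient's ranking is the highest-ranking presentation
#' they arrive with; patients with no ranked presentation are non-urgent.
#'
#' @format Character vector of the four level codes, in rank order.
#' @export
urgency_levels <- c("non_urgent", "urgent", "very_urgent", "emergent")

#' Integer rank (0-3) of SATS urgency level codes
#'
#' @param urgency Character vector of level codes (see [urgency_levels]).
#' @return Integer vector of ranks 0-3.
#' @export
urgency_rank <- function(urgency) {
  r <- match(urgency, urgency_levels) - 1L
  bad <- !is.na(urgency) & is.na(r)
  if (any(bad)) {
    stop_khds(sprintf("unknown urgency level: %s",
                      paste(unique(urgency[bad]), collapse = ", ")),
              "khds_taxonomy_error")
  }
  r
}

# The 20 presentations observed in the study setting. Reduced level of
# consciousness is re-defined as coma (responsive only to pain or
# unresponsive). Presentations that could not be recorded (post-ictal,
# compound fracture, dislocations, stabbings, eye injuries,
# pregnancy-related) are deliberately absent: unknown codes are an error,
# never silently non-urgent.
sats_presentations <- data.frame(
  code = c(
    "hypoglycaemia", "apnoea_pre_arrest", "fitting",
    "severe_breathlessness", "head_injury", "high_energy_transfer_injury",
    "severe_pain", "suspected_stroke", "haemoptysis_uncontrolled_bleeding",
    "coma", "diabetic_ketoacidosis", "burns", "poisoning", "chest_pain",
    "abdominal_pain", "diabetes_no_ketoacidosis", "moderate_pain",
    "suspected_fracture", "controlled_bleeding", "vomiting"),
  label = c(
    "Hypoglycaemia", "Apnoea/Pre-arrest", "Fitting",
    "Severe breathlessness",
    "Head injury - open wound and/or suspected skull fracture",
    "High energy transfer injury", "Severe pain", "Suspected stroke",
    "Haemoptysis or uncontrolled bleeding",
    "Coma (responsive only to pain or unresponsive)",
    "Diabetic keto-acidosis", "Burns", "Poisoning", "Chest pain",
    "Abdominal pain", "Diabetes without keto-acidosis", "Moderate pain",
    "Suspected fracture", "Controlled bleeding", "Vomiting"),
  urgency = c(rep("emergent", 3), rep("very_urgent", 11), rep("urgent", 6)),
  stringsAsFactors = FALSE)

#' The SATS presentation taxonomy
#'
#' Returns the 20 labelled presentations observed in the study setting:
#' 3 emergent, 11 very urgent (including coma, which replaces "reduced
#' level of consciousness"), and 6 urgent. Everything else presents as
#' non-urgent, carried by the pseudo-code `"non_urgent"`.
#'
#' @param include_non_urgent If `TRUE`, append the `non_urgent`
#'   pseudo-presentation row.
#' @return Data frame with columns `code`, `label`, `urgency`.
#' @export
sats_taxonomy <- function(include_non_urgent = FALSE) {
  tx <- sats_presentations
  if (include_non_urgent) {
    tx <- rbind(tx, data.frame(code = "non_urgent",
                               label = "No urgency-ranked presentation",
                               urgency = "non_urgent"))
  }
  tx
}

#' Export the taxonomy as JSON
#'
#' @param path Output path for the JSON file.
#' @return Invisibly, `path`.
#' @export
write_sats_taxonomy_json <- function(path) {
  jsonlite::write_json(sats_taxonomy(), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Rank a patient by SATS presentation urgency
#'
#' A patient presenting with several ranked complaints takes the ranking of
#' the highest-ranking one; a patient with no ranked presentation (empty
#' list, or only the `non_urgent` pseudo-code) is non-urgent. Order and
#' duplication of codes are irrelevant.
#'
#' @param codes Character vector of presentation codes for one patient.
#' @return A single urgency level code (see [urgency_levels]).
#' @export
#' @examples
#' rank_patient(c("abdominal_pain", "severe_breathlessness")) # very_urgent
#' rank_patient(character())                                  # non_urgent
rank_patient <- function(codes) {
  codes <- codes[!is.na(codes) & codes != "" & codes != "non_urgent"]
  if (!length(codes)) return("non_urgent")
  tx <- sats_presentations
  unknown <- setdiff(codes, tx$code)
  if (length(unknown)) {
    stop_khds(paste("unknown SATS presentation code:",
                    paste(unknown, collapse = ", ")),
              "khds_taxonomy_error")
  }
  urgency_levels[max(urgency_rank(tx$urgency[match(codes, tx$code)])) + 1L]
}

#' SATS urgency ranking for every record of a cohort
#'
#' Splits each record's semicolon-separated `presentations` field and
#' applies [rank_patient]. Records with `NA` presentations (never ranked,
#' e.g. assessed before SATS data collection began) get `NA` and are
#' excluded from SATS analyses.
#'
#' @param records Cohort data frame.
#' @return Character vector of urgency level codes (or `NA`).
#' @export
rank_cohort <- function(records) {
  vapply(records$presentations, function(p) {
    if (is.na(p)) return(NA_character_)
    rank_patient(strsplit(p, ";", fixed = TRUE)[[1]])
  }, character(1), USE.NAMES = FALSE)
}
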