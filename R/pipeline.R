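# Pipeline drivers tying the stages together: simulate a cohort to disk
# with provenance, and run the full analysis (cohort summaries,
# discrimination comparisons, concordance cross-tab, discordance and
# score-level breakdowns) with report rendering to CSV/JSON/markdown.

#' Simulate a cohort and write it to disk with provenance
#'
#' Writes the cohort CSV plus a sidecar `<path>.provenance.json` recording
#' the seed, the full generator configuration, its MD5 hash and the
#' package version — enough to reproduce the file exactly.
#'
#' @param path Output CSV path.
#' @param config Generator configuration (default [default_config]).
#' @param seed Integer seed.
#' @return Invisibly, the cohort data frame.
#' @export
simulate_cohort_file <- function(path, config = default_config(), seed = 1) {
  records <- generate_cohort(config, seed)
  write_cohort(records, path)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  prov <- list(seed = seed,
               n = nrow(records),
               config_md5 = unname(tools::md5sum(tmp)),
               config = unclass(config),
               package_version = as.character(utils::packageVersion("khds")))
  unlink(tmp)
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(records)
}

#' Run the full triage analysis over a cohort
#'
#' Executes every analysis stage: per-variant cohort summaries on each
#' variant's complete-case analysis set, the discrimination comparison
#' table for 24-hour death and admission, the score x SATS-urgency
#' cross-tab with acuity discordance and discordant-group outcomes, and
#' the outcome breakdown by score. When `out_dir` is given, reports are
#' written there in the requested formats.
#'
#' @param records Cohort data frame, or a path to a cohort CSV.
#' @param variant Score variant driving the concordance analyses
#'   (default `"sat"`).
#' @param scorers Comparison scorers for the discrimination table.
#' @param cut High-acuity cut in points (default 2).
#' @param lower_levels Lower-discordance denominator levels.
#' @param out_dir Optional output directory for rendered reports.
#' @param formats Any of `"csv"`, `"json"`, `"md"`.
#' @return List: `summaries` (per-variant [cohort_summary]),
#'   `discrimination`, `crosstab`, `discordance`, `discordant_outcomes`,
#'   `breakdown`, `exclusions` (per-variant excluded record counts).
#' @export
run_analysis <- function(records, variant = "sat",
                         scorers = c("resp", "months", "sats"),
                         cut = 2,
                         lower_levels = c("urgent", "very_urgent"),
                         out_dir = NULL, formats = c("csv", "json", "md")) {
  if (is.character(records)) records <- read_cohort(records)
  if (nrow(records) == 0) {
    stop_khds("empty cohort: nothing to analyse", "khds_argument_error")
  }
  summaries <- list()
  exclusions <- list()
  for (v in khds_variants) {
    pts <- compute_khds(records, v)$points
    exclusions[[v]] <- sum(is.na(pts))
    summaries[[v]] <- cohort_summary(records[!is.na(pts), , drop = FALSE])
  }
  ranked <- !is.na(rank_cohort(records))
  exclusions$sats <- sum(!ranked)
  if (any(ranked)) {
    summaries$sats <- cohort_summary(records[ranked, , drop = FALSE])
  }
  ct <- crosstab_khds_sats(records, variant)
  res <- list(
    summaries = summaries,
    discrimination = discrimination_table(records, scorers),
    crosstab = ct,
    discordance = acuity_discordance(ct, cut, lower_levels),
    discordant_outcomes = discordant_outcomes(records, variant, cut),
    breakdown = breakdown_by_score(records, variant, cut),
    exclusions = exclusions)
  if (!is.null(out_dir)) write_reports(res, out_dir, formats)
  res
}

summary_frame <- function(summaries) {
  do.call(rbind, lapply(names(summaries), function(v) {
    s <- summaries[[v]]
    data.frame(analysis_set = v, n = s$n,
               mean_age = round_half_up(s$mean_age, 1),
               sd_age = round_half_up(s$sd_age, 1),
               median_age = s$median_age,
               iqr_low = s$iqr_age[1], iqr_high = s$iqr_age[2],
               n_male = s$n_male, pct_male = s$pct_male,
               n_admitted = s$n_admitted, pct_admitted = s$pct_admitted,
               n_died_24h = s$n_died_24h, pct_died_24h = s$pct_died_24h)
  }))
}

crosstab_frame <- function(crosstab) {
  m <- unclass(crosstab)
  df <- as.data.frame.table(m, responseName = "count")
  names(df) <- c("points", "urgency", "count")
  df$points <- as.integer(as.character(df$points))
  df[order(df$points, urgency_rank(as.character(df$urgency))), ]
}

display_discrimination <- function(disc) {
  out <- disc
  out$auc <- sprintf("%.3f", disc$auc)
  out$se <- sprintf("%.3f", disc$se)
  out$ref_auc <- ifelse(is.na(disc$ref_auc), "",
                        sprintf("%.3f", disc$ref_auc))
  out$ref_se <- ifelse(is.na(disc$ref_se), "", sprintf("%.3f", disc$ref_se))
  out$p <- ifelse(is.na(disc$p), "", format_p(disc$p))
  out
}

#' Write analysis reports to a directory
#'
#' @param res Result list from [run_analysis].
#' @param out_dir Output directory (created if needed).
#' @param formats Any of `"csv"`, `"json"`, `"md"`.
#' @return Invisibly, `out_dir`.
#' @export
write_reports <- function(res, out_dir, formats = c("csv", "json", "md")) {
  formats <- match.arg(formats, c("csv", "json", "md"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    cohort_summary = summary_frame(res$summaries),
    discrimination = display_discrimination(res$discrimination),
    crosstab = crosstab_frame(res$crosstab))
  for (nm in names(tables)) {
    if ("csv" %in% formats) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    if ("md" %in% formats) {
      writeLines(markdown_table(tables[[nm]]),
                 file.path(out_dir, paste0(nm, ".md")))
    }
  }
  if ("json" %in% formats) {
    jsonlite::write_json(
      list(discordance = unclass(res$discordance),
           discordant_outcomes = res$discordant_outcomes,
           breakdown = res$breakdown,
           exclusions = res$exclusions),
      file.path(out_dir, "concordance.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
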