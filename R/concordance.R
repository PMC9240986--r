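# Analysis layer: cohort summaries, discrimination comparisons between
# score variants, the score-points x SATS-urgency cross-tabulation, acuity
# discordance, and outcome breakdowns by score.

#' Construct a score-points x SATS-urgency cross-tabulation
#'
#' @param counts 4x4 non-negative count matrix, rows = disposition-score
#'   points 0-3, columns = the four urgency levels in rank order.
#' @return Matrix of class `khds_crosstab` with canonical dimnames.
#' @export
khds_crosstab <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4)) || any(counts < 0)) {
    stop_khds("crosstab must be a 4x4 matrix of non-negative counts",
              "khds_argument_error")
  }
  dimnames(counts) <- list(points = as.character(0:3),
                           urgency = urgency_levels)
  structure(counts, class = c("khds_crosstab", "matrix"))
}

#' Cross-tabulate disposition-score points against SATS urgency
#'
#' Counts, over records with both a computable score for `variant` and a
#' SATS ranking, how many fall in each (points, urgency) cell. Records
#' missing either axis are excluded; the exclusion count is attached as
#' attribute `n_excluded`.
#'
#' @param records Cohort data frame.
#' @param variant One of [khds_variants].
#' @return A [khds_crosstab] matrix.
#' @export
crosstab_khds_sats <- function(records, variant = "sat") {
  points <- compute_khds(records, variant)$points
  urgency <- rank_cohort(records)
  keep <- !is.na(points) & !is.na(urgency)
  counts <- table(factor(points[keep], levels = 0:3),
                  factor(urgency[keep], levels = urgency_levels))
  out <- khds_crosstab(unclass(counts))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Published reference cross-tabulation of score points vs SATS urgency
#'
#' Loads the packaged counts of the published 7,500-patient
#' cross-tabulation of disposition-score points (0-3) against SATS urgency
#' rankings — the fixture every concordance analysis can be checked
#' against. Row totals are 6,926 non-urgent, 156 urgent, 395 very urgent
#' and 23 emergent.
#'
#' @return A [khds_crosstab] matrix with grand total 7,500.
#' @export
reference_crosstab <- function() {
  path <- system.file("extdata", "sats_khds_crosstab_published.csv",
                      package = "khds", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- matrix(0L, 4, 4)
  m[cbind(df$points + 1L, urgency_rank(df$urgency) + 1L)] <- df$count
  khds_crosstab(m)
}

#' Write the reference cross-tabulation counts to a CSV file
#'
#' Emits the packaged 16-cell (points, urgency, count) fixture, e.g. for
#' use outside the package. Re-emission is byte-identical.
#'
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_crosstab <- function(path) {
  src <- system.file("extdata", "sats_khds_crosstab_published.csv",
                     package = "khds", mustWork = TRUE)
  file.copy(src, path, overwrite = TRUE)
  invisible(path)
}

#' Acuity discordance between the disposition score and SATS
#'
#' Higher-acuity discordance: patients the score flags (points at or above
#' `cut`, default 2) whom SATS ranks non-urgent, as a share of all
#' non-urgent patients. Lower-acuity discordance: patients SATS ranks in
#' `lower_levels` (default urgent + very urgent) whom the score leaves
#' below the cut, as a share of patients at those levels. Emergent can be
#' added to `lower_levels`; on the published reference cross-tab this
#' changes nothing, as no emergent patient scored below 2.
#'
#' @param crosstab A [khds_crosstab].
#' @param cut High-score threshold in points (default 2).
#' @param lower_levels Urgency levels forming the lower-discordance
#'   denominator.
#' @return List of class `khds_discordance`: `n_higher`, `pct_higher`,
#'   `n_lower`, `pct_lower`, `non_urgent_total`, `lower_denominator`.
#' @export
acuity_discordance <- function(crosstab, cut = 2,
                               lower_levels = c("urgent", "very_urgent")) {
  stopifnot(inherits(crosstab, "khds_crosstab"))
  lower_levels <- match.arg(lower_levels, urgency_levels, several.ok = TRUE)
  m <- unclass(crosstab)
  hi <- (0:3) >= cut
  non_urgent_total <- sum(m[, "non_urgent"])
  lower_denominator <- sum(m[, lower_levels, drop = FALSE])
  if (non_urgent_total == 0 || lower_denominator == 0) {
    stop_khds("undefined discordance percentage: empty denominator group",
              "khds_degenerate_error")
  }
  n_higher <- sum(m[hi, "non_urgent"])
  n_lower <- sum(m[!hi, lower_levels, drop = FALSE])
  structure(list(
    n_higher = n_higher,
    pct_higher = percent_of(n_higher, non_urgent_total),
    n_lower = n_lower,
    pct_lower = percent_of(n_lower, lower_denominator),
    non_urgent_total = non_urgent_total,
    lower_denominator = lower_denominator,
    cut = cut, lower_levels = lower_levels), class = "khds_discordance")
}

#' @export
print.khds_discordance <- function(x, ...) {
  cat(sprintf(
    "Higher acuity than SATS: %d of %d non-urgent patients (%.1f%%)\n",
    x$n_higher, x$non_urgent_total, x$pct_higher))
  cat(sprintf(
    "Lower acuity than SATS:  %d of %d %s patients (%.1f%%)\n",
    x$n_lower, x$lower_denominator,
    paste(x$lower_levels, collapse = "/"), x$pct_lower))
  invisible(x)
}

#' Outcomes of the higher-acuity discordant group
#'
#' Restricts the cohort to patients scored at or above `cut` by the given
#' variant but ranked non-urgent by SATS, and summarises their outcomes:
#' admissions, deaths within 24 h, later in-hospital deaths, and the share
#' of admitted patients who died (early plus late deaths over admissions).
#'
#' @inheritParams crosstab_khds_sats
#' @param cut High-score threshold in points (default 2).
#' @return List: `n_group`, `n_admitted`, `pct_admitted`, `n_died_24h`,
#'   `pct_died_24h`, `n_died_later`, `pct_died_of_admitted` (`NA` when no
#'   one was admitted).
#' @export
discordant_outcomes <- function(records, variant = "sat", cut = 2) {
  points <- compute_khds(records, variant)$points
  urgency <- rank_cohort(records)
  grp <- !is.na(points) & !is.na(urgency) &
    points >= cut & urgency == "non_urgent"
  g <- records[grp, , drop = FALSE]
  n_admitted <- sum(g$admitted)
  n_died_24h <- sum(g$died_within_24h)
  n_died_later <- sum(g$died_in_hospital & !g$died_within_24h)
  list(n_group = nrow(g),
       n_admitted = n_admitted,
       pct_admitted = percent_of(n_admitted, nrow(g)),
       n_died_24h = n_died_24h,
       pct_died_24h = percent_of(n_died_24h, nrow(g)),
       n_died_later = n_died_later,
       pct_died_of_admitted = if (n_admitted > 0) {
         percent_of(n_died_24h + n_died_later, n_admitted)
       } else NA_real_)
}

#' Descriptive summary of a cohort
#'
#' Age (mean/SD, median, IQR by linear-interpolation percentiles), sex,
#' admission and 24-hour mortality counts with percentages.
#'
#' @param records Non-empty cohort data frame.
#' @return List of class `khds_cohort_summary`.
#' @export
cohort_summary <- function(records) {
  n <- nrow(records)
  if (n == 0) stop_khds("empty cohort", "khds_argument_error")
  q <- stats::quantile(records$age, c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  n_male <- sum(records$sex == "male")
  n_admitted <- sum(records$admitted)
  n_died_24h <- sum(records$died_within_24h)
  structure(list(
    n = n,
    mean_age = mean(records$age),
    sd_age = stats::sd(records$age),
    median_age = q[2], iqr_age = c(q[1], q[3]),
    n_male = n_male, pct_male = percent_of(n_male, n),
    n_admitted = n_admitted, pct_admitted = percent_of(n_admitted, n),
    n_died_24h = n_died_24h, pct_died_24h = percent_of(n_died_24h, n)),
    class = "khds_cohort_summary")
}

#' @export
print.khds_cohort_summary <- function(x, ...) {
  cat(sprintf("n = %d\n", x$n))
  cat(sprintf("Age: %.1f SD %.1f, median %g (IQR %g-%g)\n",
              x$mean_age, x$sd_age, x$median_age,
              x$iqr_age[1], x$iqr_age[2]))
  cat(sprintf("Male: %d (%.1f%%)\n", x$n_male, x$pct_male))
  cat(sprintf("Admitted: %d (%.1f%%)\n", x$n_admitted, x$pct_admitted))
  cat(sprintf("Died within 24 h: %d (%.1f%%)\n",
              x$n_died_24h, x$pct_died_24h))
  invisible(x)
}

score_for <- function(records, scorer) {
  if (scorer == "sats") {
    urgency_rank(rank_cohort(records))
  } else {
    compute_khds(records, scorer)$points
  }
}

outcome_for <- function(records, outcome) {
  switch(outcome,
         death_24h = records$died_within_24h,
         admitted = records$admitted,
         stop_khds(paste("unknown outcome:", outcome),
                   "khds_argument_error"))
}

#' Discrimination comparison table across score variants and SATS
#'
#' For each outcome (24-hour death, hospital admission) and each
#' comparison scorer, computes the c statistic on that scorer's own
#' complete-case subset, recomputes the reference variant's c statistic on
#' the *same subset* (the two are only comparable on common patients —
#' which is why the reference c statistic printed beside a late-starting
#' variant differs from its full-cohort value), and reports the one-tailed
#' z-test p-value. The SATS urgency ranking enters as a 4-level ordinal
#' score of its own.
#'
#' @param records Cohort data frame.
#' @param scorers Comparison scorers: any of `"resp"`, `"months"`,
#'   `"sats"`.
#' @param reference Reference variant (default `"sat"`).
#' @param outcomes Outcomes to tabulate.
#' @return Data frame, one row per (outcome, scorer) including a row for
#'   the reference itself on its full analysis set: columns `outcome`,
#'   `scorer`, `n`, `auc`, `se`, `ref_auc`, `ref_se`, `p` (reference row:
#'   `NA` comparison fields).
#' @export
discrimination_table <- function(records,
                                 scorers = c("resp", "months", "sats"),
                                 reference = "sat",
                                 outcomes = c("death_24h", "admitted")) {
  ref_scores <- score_for(records, reference)
  rows <- list()
  for (outcome in outcomes) {
    y <- outcome_for(records, outcome)
    ref_keep <- !is.na(ref_scores)
    if (length(unique(y[ref_keep])) < 2) {
      # outcome class absent: the whole outcome block is non-computable
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcome, scorer = reference, n = sum(ref_keep),
        auc = NA_real_, se = NA_real_,
        ref_auc = NA_real_, ref_se = NA_real_, p = NA_real_)
      next
    }
    ref_full <- c_statistic(ref_scores[ref_keep], y[ref_keep])
    rows[[length(rows) + 1]] <- data.frame(
      outcome = outcome, scorer = reference, n = sum(ref_keep),
      auc = ref_full$auc, se = ref_full$se,
      ref_auc = NA_real_, ref_se = NA_real_, p = NA_real_)
    for (scorer in scorers) {
      s <- score_for(records, scorer)
      keep <- !is.na(s) & !is.na(ref_scores)
      if (length(unique(y[keep])) < 2) {
        rows[[length(rows) + 1]] <- data.frame(
          outcome = outcome, scorer = scorer, n = sum(keep),
          auc = NA_real_, se = NA_real_,
          ref_auc = NA_real_, ref_se = NA_real_, p = NA_real_)
        next
      }
      roc <- c_statistic(s[keep], y[keep])
      ref_sub <- c_statistic(ref_scores[keep], y[keep])
      cmp <- compare_c_statistics(roc, ref_sub)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcome, scorer = scorer, n = sum(keep),
        auc = roc$auc, se = roc$se,
        ref_auc = ref_sub$auc, ref_se = ref_sub$se, p = cmp$p)
    }
  }
  do.call(rbind, rows)
}

#' Outcome breakdown by score level
#'
#' Per score level (0-3): patient count, admissions, deaths within 24 h,
#' and later in-hospital deaths; plus two derived shares — the proportion
#' of admissions scoring below `cut` points, and the proportion of
#' 24-hour deaths whose respiratory component was positive (for the
#' saturation-based variants, the share of the dead with SpO2 < 94\%).
#'
#' @inheritParams crosstab_khds_sats
#' @param cut Low-score threshold for the admissions share (default 2).
#' @return List: `by_score` data frame (4 rows), `n_admitted_below_cut`,
#'   `pct_admitted_below_cut`, `pct_deaths_resp_positive` (`NA` with no
#'   deaths).
#' @export
breakdown_by_score <- function(records, variant = "sat", cut = 2) {
  sc <- compute_khds(records, variant)
  keep <- !is.na(sc$points)
  r <- records[keep, , drop = FALSE]
  pts <- sc$points[keep]
  resp <- sc$respiratory_point[keep]
  f <- factor(pts, levels = 0:3)
  by_score <- data.frame(
    points = 0:3,
    n = as.integer(table(f)),
    n_admitted = as.integer(tapply(r$admitted, f, sum, default = 0)),
    n_died_24h = as.integer(tapply(r$died_within_24h, f, sum, default = 0)),
    n_died_later = as.integer(tapply(r$died_in_hospital & !r$died_within_24h,
                                     f, sum, default = 0)))
  n_admitted <- sum(by_score$n_admitted)
  n_low <- sum(by_score$n_admitted[by_score$points < cut])
  n_deaths <- sum(r$died_within_24h)
  list(by_score = by_score,
       n_admitted_below_cut = n_low,
       pct_admitted_below_cut = if (n_admitted > 0) {
         percent_of(n_low, n_admitted)
       } else NA_real_,
       pct_deaths_resp_positive = if (n_deaths > 0) {
         percent_of(sum(resp[r$died_within_24h]), n_deaths, digits = 0)
       } else NA_real_)
}
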