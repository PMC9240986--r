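#!/usr/bin/env Rscript
# Stage 2 — per-variant analysis sets.
#
# Each score variant started on a different date, so each has its own
# complete-case analysis set. Summarises demographics, admission and
# 24-hour mortality per set and writes the table to results/.

suppressPackageStartupMessages(library(khds))

cohort <- read_cohort("results/cohort.csv")

rows <- lapply(c(sat = "sat", months = "months", resp = "resp"),
               function(v) {
  pts <- compute_khds(cohort, v)$points
  cohort_summary(cohort[!is.na(pts), , drop = FALSE])
})
rows$sats <- cohort_summary(cohort[!is.na(rank_cohort(cohort)), ,
                                   drop = FALSE])

for (v in names(rows)) {
  cat("\n==", v, "analysis set ==\n")
  print(rows[[v]])
}

tab <- do.call(rbind, lapply(names(rows), function(v) {
  s <- rows[[v]]
  data.frame(analysis_set = v, n = s$n,
             mean_age = round_half_up(s$mean_age, 1),
             sd_age = round_half_up(s$sd_age, 1),
             pct_male = s$pct_male, pct_admitted = s$pct_admitted,
             pct_died_24h = s$pct_died_24h)
}))
write.csv(tab, "results/cohort_summary.csv", row.names = FALSE)
cat("\nWrote results/cohort_summary.csv\n")
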