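#!/usr/bin/env Rscript
# Stage 4 — acuity concordance between the score and SATS.
#
# Cross-tabulates score points against SATS urgency for the ranked
# sub-population of the simulated cohort, summarises acuity discordance
# (high score but non-urgent rank; urgent-or-above rank but low score)
# and the outcomes of the higher-acuity discordant group, and repeats the
# discordance analysis on the packaged published cross-tab for reference.

suppressPackageStartupMessages(library(khds))

cohort <- read_cohort("results/cohort.csv")

ct <- crosstab_khds_sats(cohort, "sat")
cat("== Simulated ranked sub-population ==\n")
print(unclass(ct))
cat(sprintf("(%d of %d records unranked and excluded)\n\n",
            attr(ct, "n_excluded"), nrow(cohort)))
print(acuity_discordance(ct))

out <- discordant_outcomes(cohort, "sat")
cat(sprintf(
  "\nHigher-acuity discordant group: %d patients; %d (%.1f%%) admitted;\n",
  out$n_group, out$n_admitted, out$pct_admitted))
cat(sprintf(
  "%d died within 24 h (%.1f%%); of the admitted, %.1f%% died in hospital.\n",
  out$n_died_24h, out$pct_died_24h, out$pct_died_of_admitted))

b <- breakdown_by_score(cohort, "sat")
cat("\n== Outcomes by score level ==\n")
print(b$by_score, row.names = FALSE)
cat(sprintf("Admissions below two points: %d (%.1f%% of admissions)\n",
            b$n_admitted_below_cut, b$pct_admitted_below_cut))
cat(sprintf("24-h deaths with SpO2 < 94: %.0f%%\n",
            b$pct_deaths_resp_positive))

cat("\n== Published reference cross-tab ==\n")
print(acuity_discordance(reference_crosstab()))

res <- run_analysis(cohort, out_dir = "results/reports")
cat("\nFull report set written to results/reports/\n")
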