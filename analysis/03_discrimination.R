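#!/usr/bin/env Rscript
# Stage 3 — discrimination of the score variants and SATS.
#
# For 24-hour death and hospital admission: c statistic with
# Hanley-McNeil SE for the default saturation-based score on its full
# analysis set, then each alternative scorer (respiratory-rate variant,
# months-backwards variant, SATS urgency as a 4-level ordinal score) on
# its own complete-case subset, with the reference recomputed on that
# same subset and a one-tailed z comparison.

suppressPackageStartupMessages(library(khds))

cohort <- read_cohort("results/cohort.csv")
tab <- discrimination_table(cohort)

disp <- tab
disp$auc <- sprintf("%.3f", disp$auc)
disp$se <- sprintf("%.3f", disp$se)
disp$ref_auc <- ifelse(is.na(tab$ref_auc), "", sprintf("%.3f", tab$ref_auc))
disp$ref_se <- ifelse(is.na(tab$ref_se), "", sprintf("%.3f", tab$ref_se))
disp$p <- ifelse(is.na(tab$p), "", format_p(tab$p))
print(disp, row.names = FALSE)

write.csv(disp, "results/discrimination.csv", row.names = FALSE)
writeLines(markdown_table(disp), "results/discrimination.md")
cat("\nWrote results/discrimination.{csv,md}\n")
cat("Note: each comparison row reports the reference score recomputed on\n")
cat("that scorer's own (later-starting, smaller) analysis subset.\n")
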