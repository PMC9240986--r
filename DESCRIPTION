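Package: khds
Title: Triage Disposition Scoring and Discrimination Analysis for Emergency Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores emergency-department presentations with the Kitovu
    Hospital Disposition Score (KHDS) in its three variants (oxygen
    saturation, respiratory rate, and months-backwards mental-status
    assessments), ranks presentations with the South African Triage Scale
    (SATS) urgency taxonomy, and quantifies score discrimination for
    24-hour mortality and hospital admission using the c statistic with
    the Hanley-McNeil standard error. Includes acuity-concordance
    cross-tabulation between KHDS points and SATS rankings, a seedable
    synthetic-cohort generator calibrated to published score-class
    prevalences and outcome rates, cohort CSV round-trip input/output,
    and report rendering for the standard cohort, discrimination and
    concordance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
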