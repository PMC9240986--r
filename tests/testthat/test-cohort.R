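test_that("mobility point is awarded for any gait short of stable and independent", {
  expect_identical(mobility_point("stable_independent"), 0L)
  expect_identical(mobility_point(c("unsteady", "uses_aid",
                                    "needs_help", "bedridden")),
                   rep(1L, 4))
  expect_error(mobility_point("sprinting"), class = "khds_validation_error")
  expect_identical(mobility_point(NA_character_), NA_integer_)
})

test_that("subjective mental status requires all four of alert/attentive/calm/coherent", {
  rec <- make_record()
  expect_identical(mental_point(rec, "sat"), 0L)
  expect_identical(mental_point(make_record(coherent = FALSE), "sat"), 1L)
  expect_identical(mental_point(make_record(calm = FALSE), "resp"), 1L)
  # single failing flag scores the point even with the rest normal
  for (flag in c("alert", "attentive", "calm", "coherent")) {
    args <- stats::setNames(list(FALSE), flag)
    expect_identical(mental_point(do.call(make_record, args), "sat"), 1L)
  }
})

test_that("months-backwards variant reads the objective test, not the subjective flags", {
  expect_identical(
    mental_point(make_record(months_backwards_pass = FALSE), "months"), 1L)
  # subjectively impaired but passes months-backwards: no point for KHDSm
  expect_identical(
    mental_point(make_record(coherent = FALSE,
                             months_backwards_pass = TRUE), "months"), 0L)
  rec <- make_record(months_backwards_pass = NA)
  expect_identical(mental_point(rec, "months"), NA_integer_)
  expect_error(mental_point(rec, "months", on_missing = "error"),
               class = "khds_missing_component")
})

test_that("respiratory point uses strict thresholds: SpO2 < 94, rate > 23", {
  expect_identical(respiratory_point(make_record(spo2 = 93), "sat"), 1L)
  expect_identical(respiratory_point(make_record(spo2 = 94), "sat"), 0L)
  expect_identical(respiratory_point(make_record(resp_rate = 24), "resp"), 1L)
  expect_identical(respiratory_point(make_record(resp_rate = 23), "resp"), 0L)
  # the months variant reads oxygen saturation for this component
  expect_identical(respiratory_point(make_record(spo2 = 90), "months"), 1L)
  expect_error(
    respiratory_point(make_record(resp_rate = NA), "resp",
                      on_missing = "error"),
    class = "khds_missing_component")
})

test_that("the score sums its three components", {
  expect_identical(compute_khds(make_record(), "sat")$points, 0L)
  worst <- make_record(coherent = FALSE, gait = "bedridden", spo2 = 88)
  expect_identical(compute_khds(worst, "sat")$points, 3L)
  mob_only <- make_record(gait = "uses_aid", spo2 = 95)
  res <- compute_khds(mob_only, "sat")
  expect_identical(res$points, 1L)
  expect_identical(res$mobility_point, 1L)
  expect_identical(res$mental_point + res$respiratory_point, 0L)
  # missing component excludes the record (NA), never imputes
  expect_identical(compute_khds(make_record(spo2 = NA), "sat")$points,
                   NA_integer_)
  expect_identical(compute_khds(make_record(spo2 = NA), "resp")$points, 0L)
})

test_that("worsening any single component never decreases the score", {
  set.seed(42)
  for (i in 1:50) {
    base <- make_record(
      alert = sample(c(TRUE, FALSE), 1),
      coherent = sample(c(TRUE, FALSE), 1),
      gait = sample(gait_levels, 1),
      spo2 = sample(88:99, 1),
      resp_rate = sample(12:40, 1),
      months_backwards_pass = sample(c(TRUE, FALSE), 1))
    for (v in khds_variants) {
      p0 <- compute_khds(base, v)$points
      worse <- base
      worse$alert <- FALSE
      worse$months_backwards_pass <- FALSE
      expect_gte(compute_khds(worse, v)$points, p0)
      worse <- base; worse$gait <- "bedridden"
      expect_gte(compute_khds(worse, v)$points, p0)
      worse <- base; worse$spo2 <- 90; worse$resp_rate <- 30
      expect_gte(compute_khds(worse, v)$points, p0)
      expect_true(compute_khds(base, v)$points %in% 0:3)
    }
  }
})

test_that("saturation and respiratory-rate variants agree when both thresholds align", {
  set.seed(7)
  for (i in 1:25) {
    deranged <- sample(c(TRUE, FALSE), 1)
    rec <- make_record(
      calm = sample(c(TRUE, FALSE), 1),
      gait = sample(gait_levels, 1),
      spo2 = if (deranged) sample(85:93, 1) else sample(94:99, 1),
      resp_rate = if (deranged) sample(24:40, 1) else sample(12:23, 1))
    expect_identical(compute_khds(rec, "sat")$points,
                     compute_khds(rec, "resp")$points)
  }
})

test_that("eligibility is non-pregnant and age 12 or older, inclusive", {
  coh <- make_cohort(list(age = 12L), list(age = 11L),
                     list(age = 30L, pregnant = TRUE), list(age = 90L))
  expect_identical(is_eligible(coh), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("cohort CSV round trip is lossless", {
  coh <- make_cohort(
    list(),
    list(age = 77L, sex = "female", gait = "bedridden", spo2 = 89,
         resp_rate = NA_real_, months_backwards_pass = NA,
         presentations = "coma;abdominal_pain", admitted = TRUE,
         died_within_24h = TRUE, died_in_hospital = TRUE,
         day_of_death = 0L),
    list(presentations = NA_character_, admitted = TRUE,
         died_in_hospital = TRUE, day_of_death = 3L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back, coh)
})

test_that("header-only files read as empty cohorts and bad rows are reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(make_cohort(list())[0, ], path)
  expect_identical(nrow(read_cohort(path)), 0L)

  bad <- make_cohort(list(), list(spo2 = 150))
  expect_error(validate_cohort(bad), "rows 2",
               class = "khds_validation_error")
  write.csv(data.frame(a = 1), path, row.names = FALSE)
  expect_error(read_cohort(path), "header",
               class = "khds_validation_error")
})

test_that("outcome nesting is enforced: deaths are admissions, early deaths are day 0", {
  expect_error(validate_cohort(make_cohort(
    list(died_within_24h = TRUE, died_in_hospital = TRUE,
         admitted = FALSE, day_of_death = 0L))),
    class = "khds_validation_error")
  expect_error(validate_cohort(make_cohort(
    list(died_within_24h = TRUE, died_in_hospital = TRUE,
         admitted = TRUE, day_of_death = 2L))),
    class = "khds_validation_error")
})
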