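test_that("the cross-tab places each scored-and-ranked patient in one cell", {
  coh <- make_cohort(
    list(coherent = FALSE, gait = "bedridden", spo2 = 88,
         presentations = "apnoea_pre_arrest"),
    list(presentations = "non_urgent"),
    list(gait = "uses_aid", presentations = "moderate_pain"),
    list(presentations = NA_character_),       # never ranked: excluded
    list(spo2 = NA_real_, presentations = "vomiting"))  # unscored: excluded
  ct <- crosstab_khds_sats(coh, "sat")
  m <- unclass(ct)
  expect_identical(sum(m), 3L)
  expect_identical(m["3", "emergent"], 1L)
  expect_identical(m["0", "non_urgent"], 1L)
  expect_identical(m["1", "urgent"], 1L)
  expect_identical(attr(ct, "n_excluded"), 2L)
})

test_that("the packaged reference cross-tab reproduces every published margin", {
  ct <- reference_crosstab()
  m <- unclass(ct)
  expect_identical(unname(colSums(m)), c(6926, 156, 395, 23))
  expect_identical(unname(rowSums(m)), c(5430, 735, 1037, 298))
  expect_equal(sum(m), 7500L)
  # no zero-point patient was ranked above non-urgent; 7 one-pointers were
  expect_equal(sum(m["0", c("urgent", "very_urgent", "emergent")]), 0L)
  expect_equal(sum(m["1", c("urgent", "very_urgent")]), 7L)
})

test_that("acuity discordance on the reference cross-tab matches the published shares", {
  d <- acuity_discordance(reference_crosstab())
  expect_equal(d$n_higher, 768L)
  expect_equal(d$pct_higher, 11.1)   # 768 of 6,926 non-urgent
  expect_equal(d$n_lower, 7L)
  expect_equal(d$lower_denominator, 551L)
  expect_equal(d$pct_lower, 1.3)     # 7 of 551 urgent or very urgent
  # adding emergent to the denominator changes nothing here: none scored < 2
  d3 <- acuity_discordance(reference_crosstab(),
                           lower_levels = c("urgent", "very_urgent",
                                            "emergent"))
  expect_equal(d3$n_lower, 7L)
})

test_that("discordance cut extremes empty one side or the other", {
  ct <- reference_crosstab()
  expect_equal(acuity_discordance(ct, cut = 0)$n_lower, 0L)
  expect_equal(acuity_discordance(ct, cut = 4)$n_higher, 0L)
  all_low <- khds_crosstab(matrix(c(100, 0, 0, 0), 4, 4))
  expect_equal(acuity_discordance(all_low)$n_higher, 0L)
})

test_that("discordant-group outcomes recount a planted cohort exactly", {
  # 4 high-score non-urgent patients: 1 early death, 1 late death, 1
  # plain admission, 1 discharge; plus 1 high-score urgent (not in group)
  hi <- list(coherent = FALSE, gait = "bedridden", spo2 = 88,
             presentations = "non_urgent")
  coh <- make_cohort(
    modifyList(hi, list(admitted = TRUE, died_within_24h = TRUE,
                        died_in_hospital = TRUE, day_of_death = 0L)),
    modifyList(hi, list(admitted = TRUE, died_in_hospital = TRUE,
                        day_of_death = 4L)),
    modifyList(hi, list(admitted = TRUE)),
    hi,
    modifyList(hi, list(presentations = "coma", admitted = TRUE)),
    list())
  out <- discordant_outcomes(coh, "sat")
  expect_identical(out$n_group, 4L)
  expect_identical(out$n_admitted, 3L)
  expect_identical(out$n_died_24h, 1L)
  expect_identical(out$n_died_later, 1L)
  expect_equal(out$pct_died_of_admitted, percent_of(2, 3))
  none <- discordant_outcomes(coh[4, , drop = FALSE], "sat")
  expect_identical(none$n_admitted, 0L)
  expect_true(is.na(none$pct_died_of_admitted))
})

test_that("published discordant-group outcome counts yield the published percentages", {
  # 3 early deaths + 22 late deaths among 407 admitted of 768
  expect_equal(percent_of(3 + 22, 407), 6.1)
  expect_equal(percent_of(407, 768), 53.0)
  expect_equal(percent_of(3, 768), 0.4)
  expect_equal(percent_of(22, 407), 5.4)
})

test_that("cohort summaries use linear-interpolation quantiles and exact shares", {
  one <- cohort_summary(make_cohort(list(age = 40L)))
  expect_equal(one$mean_age, 40)
  expect_equal(one$sd_age, NA_real_)
  three <- cohort_summary(make_cohort(list(age = 28L), list(age = 40L),
                                      list(age = 59L)))
  expect_equal(three$median_age, 40)
  expect_equal(three$iqr_age, c(34, 49.5))  # type-7 interpolation
  five <- cohort_summary(make_cohort(
    list(sex = "male"), list(sex = "male"), list(sex = "female"),
    list(sex = "female"), list(sex = "female")))
  expect_equal(five$pct_male, 40.0)
  expect_error(cohort_summary(make_cohort(list())[0, ]),
               class = "khds_argument_error")
})

test_that("the discrimination table recomputes the reference on each comparison subset", {
  cfg <- default_config(n = 4000)
  coh <- generate_cohort(cfg, seed = 3)
  tab <- discrimination_table(coh, scorers = c("months", "sats"))
  ref_adm <- tab[tab$outcome == "admitted" & tab$scorer == "sat", ]
  row_m <- tab[tab$outcome == "admitted" & tab$scorer == "months", ]
  # the months subset starts later, so it is smaller and the reference
  # c statistic recomputed there differs from its full-cohort value
  expect_lt(row_m$n, ref_adm$n)
  expect_false(isTRUE(all.equal(row_m$ref_auc, ref_adm$auc)))
  expect_true(all(tab$p[!is.na(tab$p)] > 0 & tab$p[!is.na(tab$p)] <= 0.5))
  # a scorer compared with itself on an identical subset is a wash
  pts <- compute_khds(coh, "sat")$points
  self <- compare_c_statistics(
    c_statistic(pts, coh$admitted), c_statistic(pts, coh$admitted))
  expect_equal(self$p, 0.5)
})

test_that("the score-level breakdown recovers planted outcome structure", {
  sick <- list(coherent = FALSE, gait = "bedridden", spo2 = 88,
               admitted = TRUE)
  dead2 <- list(coherent = FALSE, gait = "needs_help", spo2 = 97,
                admitted = TRUE, died_within_24h = TRUE,
                died_in_hospital = TRUE, day_of_death = 0L)
  coh <- make_cohort(
    modifyList(sick, list(died_within_24h = TRUE, died_in_hospital = TRUE,
                          day_of_death = 0L)),
    modifyList(sick, list(died_in_hospital = TRUE, day_of_death = 9L)),
    dead2,
    list(admitted = TRUE, gait = "unsteady"),
    list(), list())
  b <- breakdown_by_score(coh, "sat")
  expect_identical(b$by_score$n, c(2L, 1L, 1L, 2L))
  expect_identical(b$by_score$n_died_24h, c(0L, 0L, 1L, 1L))
  expect_identical(b$by_score$n_died_later, c(0L, 0L, 0L, 1L))
  expect_identical(b$n_admitted_below_cut, 1L)
  expect_equal(b$pct_admitted_below_cut, 25.0)
  # one of the two early deaths carried the low-saturation point
  expect_equal(b$pct_deaths_resp_positive, 50)
  empty_deaths <- breakdown_by_score(coh[4:6, ], "sat")
  expect_true(is.na(empty_deaths$pct_deaths_resp_positive))
})

test_that("published score-level counts yield the published shares", {
  expect_equal(percent_of(39, 1804), 2.2)   # 24-h deaths among admissions
  expect_equal(percent_of(96, 1804), 5.3)   # admissions below two points
  expect_equal(percent_of(37, 39, digits = 0), 95)  # deaths with SpO2 < 94
})
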