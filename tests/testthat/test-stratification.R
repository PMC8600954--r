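test_that("WHO-2016 classes cover the full input truth table", {
  expect_identical(classify_who2016("SHH", TRUE), "SHH_TP53mut")
  expect_identical(classify_who2016("SHH", FALSE), "SHH_TP53wt")
  expect_identical(classify_who2016("NC", TRUE), "unclassifiable")
  expect_identical(classify_who2016(NA), "unclassifiable")
  truth_table <- list(
    WNT = c("WNT_activated", "WNT_activated"),
    SHH = c("SHH_TP53mut", "SHH_TP53wt"),
    Group3 = c("Group3", "Group3"),
    Group4 = c("Group4", "Group4"),
    NC = c("unclassifiable", "unclassifiable"))
  for (sg in names(truth_table)) {
    expect_identical(classify_who2016(sg, TRUE), truth_table[[sg]][1])
    expect_identical(classify_who2016(sg, FALSE), truth_table[[sg]][2])
  }
  expect_error(classify_who2016("Group5"), "Group5")
})

base_record <- list(patient_id = "X", age_years = 7.6, metastatic = FALSE,
                    incomplete_resection = FALSE, myc_amp = FALSE,
                    mycn_amp = FALSE, variant = "CLA", subgroup = "Group4",
                    surgery_to_receipt_days = 5, receipt_to_report_days = 20,
                    wnt_positive = FALSE)

test_that("eligibility rules fire with the expected reasons", {
  d <- assess_eligibility(base_record)
  expect_true(d$eligible)
  expect_identical(d$arm, "standard")
  expect_length(d$reasons, 0)

  d <- assess_eligibility(modifyList(base_record, list(mycn_amp = TRUE)))
  expect_false(d$eligible)
  expect_true("bio_high_risk" %in% d$reasons)
  expect_identical(d$arm, "none")

  d <- assess_eligibility(modifyList(base_record, list(age_years = 2.9)))
  expect_false(d$eligible)
  expect_true("age" %in% d$reasons)
  # boundary conventions: 3 is in, 23 is out
  expect_true(assess_eligibility(modifyList(base_record,
                                            list(age_years = 3)))$age_eligible)
  expect_false(assess_eligibility(modifyList(base_record,
                                             list(age_years = 23)))$age_eligible)

  d <- assess_eligibility(modifyList(base_record, list(variant = "LCA")))
  expect_true(d$bio_high_risk)
  d <- assess_eligibility(modifyList(base_record, list(subgroup = "NC")))
  expect_false(d$data_complete)
  expect_true(any(grepl("incomplete_data", d$reasons)))
  d <- assess_eligibility(modifyList(base_record,
                                     list(surgery_to_receipt_days = 11)))
  expect_false(d$turnaround_ok)
  d <- assess_eligibility(modifyList(base_record,
                                     list(metastatic = TRUE,
                                          wnt_positive = TRUE)))
  expect_false(d$eligible)
  expect_true("metastatic" %in% d$reasons)
  # eligible + WNT-consensus positive: favourable arm
  d <- assess_eligibility(modifyList(base_record, list(wnt_positive = TRUE)))
  expect_identical(d$arm, "WNT_favourable")
  # unknown fields never raise, they disqualify
  d <- assess_eligibility(modifyList(base_record, list(myc_amp = NA)))
  expect_false(d$eligible)
})

test_that("the eligibility conjunction invariant holds on random records", {
  set.seed(81)
  for (i in 1:150) {
    r <- list(patient_id = "r", age_years = runif(1, 0, 30),
              metastatic = runif(1) < .3,
              incomplete_resection = runif(1) < .2,
              myc_amp = sample(c(TRUE, FALSE, NA), 1),
              mycn_amp = sample(c(TRUE, FALSE, NA), 1),
              variant = sample(c(MB_VARIANTS, "MBNOS", NA), 1),
              subgroup = sample(c(MB_SUBGROUPS, "NC", NA), 1),
              surgery_to_receipt_days = runif(1, 0, 30),
              receipt_to_report_days = runif(1, 0, 60),
              wnt_positive = runif(1) < .1)
    d <- assess_eligibility(r)
    expect_identical(d$eligible,
                     d$age_eligible && d$data_complete && d$turnaround_ok &&
                       !d$bio_high_risk && !d$clinical_high_risk)
    expect_identical(d$arm != "none", d$eligible)
    if (!d$eligible) expect_gt(length(d$reasons), 0)
  }
})

test_that("the funnel reproduces printed counts and conserves patients", {
  decisions <- assess_cohort_eligibility(reference_case_tables()$eligibility)
  fu <- cohort_accounting(decisions)
  expect_identical(unname(fu$counts[c("total", "age_eligible",
                                      "complete_in_time",
                                      "excluded_bio_high_risk",
                                      "excluded_clinical_high_risk",
                                      "eligible")]),
                   c(135L, 115L, 88L, 13L, 36L, 39L))
  expect_equal(fu$percent_eligible$rounded, 34)
  expect_identical(unname(fu$arms[["WNT_favourable"]]), 10L)
  expect_equal(fu$percent_wnt_arm$rounded, 26)
  # stage conservation: the complete-in-time set partitions into bio-HR,
  # clinical-HR and eligible
  expect_identical(fu$counts[["complete_in_time"]],
                   fu$counts[["excluded_bio_high_risk"]] +
                     fu$counts[["excluded_clinical_high_risk"]] +
                     fu$counts[["eligible"]])
  # funnel stages never grow
  stages <- fu$counts[c("total", "age_eligible", "complete_in_time",
                        "eligible")]
  expect_true(all(diff(stages) <= 0))

  # all-ineligible cohort: zero percent with reasons throughout
  all_bad <- decisions
  all_bad$eligible <- FALSE
  all_bad$age_eligible <- FALSE
  fu0 <- cohort_accounting(all_bad)
  expect_identical(unname(fu0$counts[["eligible"]]), 0L)
  expect_error(cohort_accounting(decisions[0, ]), "nonempty")

  # random decisions match a brute-force recount
  set.seed(82)
  rnd <- data.frame(age_eligible = runif(200) < .8,
                    data_complete = runif(200) < .8,
                    turnaround_ok = runif(200) < .7,
                    bio_high_risk = runif(200) < .15,
                    clinical_high_risk = runif(200) < .3)
  rnd$eligible <- rnd$age_eligible & rnd$data_complete & rnd$turnaround_ok &
    !rnd$bio_high_risk & !rnd$clinical_high_risk
  rnd$arm <- ifelse(rnd$eligible, "standard", "none")
  fu1 <- cohort_accounting(rnd)
  expect_identical(unname(fu1$counts[["eligible"]]), sum(rnd$eligible))
  expect_identical(unname(fu1$counts[["excluded_bio_high_risk"]]),
                   sum(rnd$age_eligible & rnd$data_complete & rnd$turnaround_ok &
                         rnd$bio_high_risk))
})

test_that("risk deltas flag exactly the review-driven changes", {
  base <- list(patient_id = "X", local_variant = "CLA", metastatic = FALSE,
               incomplete_resection = FALSE, myc_amp = FALSE,
               mycn_amp = FALSE, central_variant = "CLA",
               who_class = "Group4", wnt_positive = FALSE)
  d <- compute_risk_delta(modifyList(base, list(mycn_amp = TRUE)))
  expect_identical(d$baseline_risk, "standard")
  expect_identical(d$cpr_risk, "high")
  expect_true(d$altered)

  d0 <- compute_risk_delta(base)
  expect_false(d0$altered)
  expect_identical(d0$cpr_risk, "standard")

  # favourable WNT consensus alters risk downward
  d1 <- compute_risk_delta(modifyList(base, list(wnt_positive = TRUE,
                                                 who_class = "WNT_activated")))
  expect_identical(d1$cpr_risk, "favourable")
  expect_true(d1$altered)

  # locally evident high risk stays high: not altered
  d2 <- compute_risk_delta(modifyList(base, list(metastatic = TRUE)))
  expect_identical(d2$baseline_risk, "high")
  expect_identical(d2$cpr_risk, "high")
  expect_false(d2$altered)

  # the altered flag always matches its definitional invariant
  set.seed(83)
  for (i in 1:200) {
    r <- list(patient_id = "r",
              local_variant = sample(c(MB_VARIANTS, "unassigned"), 1),
              metastatic = runif(1) < .3, incomplete_resection = runif(1) < .2,
              myc_amp = runif(1) < .1, mycn_amp = runif(1) < .1,
              central_variant = sample(c(MB_VARIANTS, "MBNOS"), 1),
              who_class = sample(c("WNT_activated", "SHH_TP53mut",
                                   "SHH_TP53wt", "Group3", "Group4",
                                   "unclassifiable"), 1),
              wnt_positive = runif(1) < .1)
    d <- compute_risk_delta(r)
    expect_identical(d$altered,
                     d$cpr_risk != "unknown" && d$cpr_risk != d$baseline_risk)
  }
})

test_that("turnaround thresholds are mean + 1 SD with strict late flags", {
  ts <- turnaround_thresholds(c(2, 4, 6))
  expect_equal(ts$mean, 4)
  expect_equal(ts$sd, 2)
  expect_equal(ts$threshold, 6)
  expect_identical(ts$n_late, 0L)  # 6 is exactly at threshold: on time

  ts2 <- turnaround_thresholds(c(2, 4, 6, 20),
                               delay_reasons = c("none", "none", "none",
                                                 "personnel"))
  expect_identical(ts2$n_late, 1L)
  expect_identical(names(ts2$late_reasons), "personnel")

  ts3 <- turnaround_thresholds(rep(5, 10))
  expect_identical(ts3$n_late, 0L)
  expect_equal(ts3$threshold, 5)

  expect_error(turnaround_thresholds(3), "2")

  # flagged fraction approximates the generating distribution's tail mass
  x <- with_seed(84, rlnorm(2000, 0, 0.5))
  ts4 <- turnaround_thresholds(x)
  p_tail <- 1 - plnorm(exp(0.125) * (1 + sqrt(exp(0.25) - 1)), 0, 0.5)
  expect_lt(abs(mean(ts4$late) - p_tail),
            3 * sqrt(p_tail * (1 - p_tail) / 2000) + 0.01)
})
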