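test_that("WNT consensus agrees with exhaustive enumeration of panel states", {
  # 3 mutation states x 3^4 measure states = 243 panels, vs the brute-force
  # completion oracle
  tri <- list(TRUE, FALSE, NA)
  for (mut in tri) for (ihc in tri) for (chr6 in tri) {
    for (meth in tri) for (rna in tri) {
      ihc_pct <- if (is.na(ihc)) NA else if (ihc) 40 else 2
      meth_lab <- if (is.na(meth)) NA else if (meth) "WNT" else "Group4"
      rna_lab <- if (is.na(rna)) NA else if (rna) "WNT" else "SHH"
      got <- call_wnt_consensus(mut, ihc_pct, chr6, meth_lab, rna_lab)
      want <- wnt_consensus_oracle(mut, c(ihc, chr6, meth, rna))
      if (is.na(mut) && all(is.na(c(ihc, chr6, meth, rna)))) {
        want <- "indeterminate"  # no call attempted on an all-unknown panel
        expect_identical(got$rule_fired, "insufficient_data")
      }
      expect_identical(got$status, want)
    }
  }
})

test_that("WNT consensus worked examples hold", {
  # mutation overrides everything
  r <- call_wnt_consensus(TRUE, 0, FALSE, "Group3", "Group4")
  expect_identical(r$status, "positive")
  expect_identical(r$rule_fired, "ctnnb1_mutation")

  # one positive measure only (IHC 15%), wild-type: negative
  r <- call_wnt_consensus(FALSE, 15, FALSE, "Group4", "Group4")
  expect_identical(r$status, "negative")

  # two molecular measures, wild-type: positive
  r <- call_wnt_consensus(FALSE, 0, TRUE, "WNT", NA)
  expect_identical(r$status, "positive")
  expect_identical(r$rule_fired, "two_or_more_measures")

  # IHC threshold is >= 10%
  expect_identical(call_wnt_consensus(FALSE, 10, TRUE, NA, NA)$status, "positive")
  expect_identical(call_wnt_consensus(FALSE, 9.9, FALSE, "Group4",
                                      "Group4")$status, "negative")

  # evidence lists each known measure exactly once
  r <- call_wnt_consensus(FALSE, 15, NA, "WNT", NA)
  expect_identical(sort(r$evidence$measure),
                   sort(c("ctnnb1_mut", "ihc", "meth_subgroup")))
})

test_that("adding a positive measure never flips positive to negative", {
  tri <- list(TRUE, FALSE, NA)
  combos <- expand.grid(mut = tri, ihc = tri, chr6 = tri, meth = tri,
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(combos))) {
    cm <- combos[i, ]
    ihc_pct <- if (is.na(cm$ihc[[1]])) NA else if (cm$ihc[[1]]) 40 else 2
    meth_lab <- if (is.na(cm$meth[[1]])) NA else if (cm$meth[[1]]) "WNT" else "Group4"
    before <- call_wnt_consensus(cm$mut[[1]], ihc_pct, cm$chr6[[1]], meth_lab,
                                 "Group4")$status
    after <- call_wnt_consensus(cm$mut[[1]], ihc_pct, cm$chr6[[1]], meth_lab,
                                "WNT")$status
    if (before == "positive") expect_identical(after, "positive")
  }
})

test_that("pathologist consensus is the majority over all vote patterns", {
  expect_true(pathologist_consensus(c(TRUE, TRUE, FALSE)))
  expect_false(pathologist_consensus(c(FALSE, FALSE, FALSE)))
  grid <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    v <- unlist(grid[i, ])
    expect_identical(pathologist_consensus(v), sum(v) >= 2)
  }
  expect_error(pathologist_consensus(c(TRUE, FALSE)), "3")
  expect_error(pathologist_consensus(c(TRUE, FALSE, NA)), "3")
})

test_that("variant reconciliation reproduces the review accounting", {
  # printed-margin fixture: 10 changed of 105 locally assigned, 30 assigned
  tab <- reference_case_tables()$variant_review
  s <- reconcile_variants(tab)
  expect_identical(s$n, 135L)
  expect_identical(s$n_local_assigned, 105L)
  expect_identical(as.integer(s$counts[c("changed", "assigned", "unresolved")]),
                   c(10L, 30L, 7L))
  expect_equal(s$percent$changed$rounded, 10)
  expect_equal(s$percent$assigned$raw, 3000 / 135, tolerance = 1e-12)
  expect_equal(s$percent$combined$rounded, 30)

  all_same <- data.frame(local_variant = rep("CLA", 12),
                         central_variant = rep("CLA", 12))
  s0 <- reconcile_variants(all_same)
  expect_equal(s0$percent$changed$raw, 0)
  expect_identical(unname(s0$counts[["concordant"]]), 12L)

  # random reviews equal a brute-force recount
  set.seed(41)
  rnd <- data.frame(
    local_variant = sample(c(MB_VARIANTS, "unassigned"), 300, replace = TRUE),
    central_variant = sample(c(MB_VARIANTS, "MBNOS"), 300, replace = TRUE))
  s1 <- reconcile_variants(rnd)
  expect_identical(sum(s1$counts), 300L)
  recount_changed <- sum(rnd$local_variant != "unassigned" &
                           rnd$central_variant != "MBNOS" &
                           rnd$local_variant != rnd$central_variant)
  recount_assigned <- sum(rnd$local_variant == "unassigned" &
                            rnd$central_variant != "MBNOS")
  expect_identical(unname(s1$counts[["changed"]]), recount_changed)
  expect_identical(unname(s1$counts[["assigned"]]), recount_assigned)
  expect_identical(unname(s1$counts[["unresolved"]]),
                   sum(rnd$central_variant == "MBNOS"))
  expect_error(reconcile_variants(rnd[0, ]), "nonempty")
})

test_that("molecular WNT measures outperform single-observer IHC on panels", {
  cfg <- quick_config(n = 400, seed = 61)
  co <- generate_cohort(cfg, apply_failures = FALSE)
  p <- co$patients
  panel <- data.frame(patient_id = p$patient_id, ctnnb1_mut = p$ctnnb1_mut,
                      ihc_nuclear_pct = p$ihc_nuclear_pct,
                      chr6_monosomy = p$chr6_monosomy,
                      meth_subgroup = p$true_subgroup,
                      rna_subgroup = p$true_subgroup,
                      stringsAsFactors = FALSE)
  cons <- call_cohort_wnt(panel)
  truth <- cons$status == "positive"
  stat <- function(calls) {
    sensitivity_specificity(build_confusion(calls, truth))
  }
  meth <- stat(panel$meth_subgroup == "WNT")
  expect_equal(meth$sensitivity$raw, 100)
  expect_equal(meth$specificity$raw, 100)
  rna <- stat(panel$rna_subgroup == "WNT")
  expect_equal(rna$sensitivity$raw, 100)
  ihc <- stat(panel$ihc_nuclear_pct >= 10)
  expect_lt(ihc$sensitivity$raw, 100)
  chr6 <- stat(panel$chr6_monosomy)
  expect_equal(chr6$specificity$raw, 100)
  expect_lt(chr6$sensitivity$raw, 100)
})
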