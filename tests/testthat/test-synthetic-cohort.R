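test_that("cohort generation is deterministic and honours the empty case", {
  cfg <- quick_config(n = 25, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL, ascii = TRUE),
                   serialize(b, NULL, ascii = TRUE))
  d <- generate_cohort(quick_config(n = 25, seed = 10))
  expect_false(identical(a$patients, d$patients))

  e <- generate_cohort(quick_config(n = 0))
  expect_s3_class(e, "mb_cohort")
  expect_identical(nrow(e$patients), 0L)
  expect_identical(ncol(e$methylation), 0L)
  expect_identical(nrow(e$ifish), 0L)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(subgroup_priors = c(WNT = .5, SHH = .2,
                                                 Group3 = .2, Group4 = .2)),
               "subgroup_priors")
  expect_error(cohort_config(failure_rates = list(low_dna = -0.1, low_rna = 0,
                                                  low_rin = 0, ifish = 0,
                                                  mlpa = 0)),
               "low_dna")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(n_probes = 300), "n_probes")
  expect_error(generate_methylation_profiles("Group5", quick_config(n = 1)),
               "Group5")
})

test_that("subgroup and biomarker frequencies recover configured rates", {
  cfg <- quick_config(n = 5000, seed = 123)
  co <- generate_cohort(cfg, apply_failures = FALSE)
  n <- nrow(co$patients)
  for (sg in MB_SUBGROUPS) {
    p <- cfg$subgroup_priors[[sg]]
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(co$patients$true_subgroup == sg) - p), tol)
  }
  # conditional biomarker rates within their subgroups
  wnt <- co$patients[co$patients$true_subgroup == "WNT", ]
  p <- cfg$biomarker_rates$chr6_monosomy[["WNT"]]
  expect_lt(abs(mean(wnt$chr6_monosomy) - p),
            3 * sqrt(p * (1 - p) / nrow(wnt)))
  shh <- co$patients[co$patients$true_subgroup == "SHH", ]
  p <- cfg$biomarker_rates$tp53_mut[["SHH"]]
  expect_lt(abs(mean(shh$tp53_mut) - p), 3 * sqrt(p * (1 - p) / nrow(shh)))
  # at most one of MYC/MYCN amplification per patient
  expect_false(any(co$patients$myc_amp & co$patients$mycn_amp))
})

test_that("methylation profiles carry the block structure the model assumes", {
  cfg <- quick_config(n = 1)
  m <- generate_methylation_profiles(rep(MB_SUBGROUPS, each = 5), cfg)
  expect_true(all(m >= 0 & m <= 1))
  expect_identical(dim(m), c(600L, 20L))

  # strong separation, low noise: nearest-centroid recovers labels > 99%
  cfg_hi <- quick_config(n = 1, signal_separation = 0.4, noise_sd = 0.05)
  labels <- with_seed(5, sample(MB_SUBGROUPS, 1000, replace = TRUE))
  beta <- with_seed(6, generate_methylation_profiles(labels, cfg_hi))
  expect_gt(mean(nearest_centroid_labels(beta, cfg_hi) == labels), 0.99)

  # null signal: profiles exchangeable, recovery at chance level
  cfg0 <- quick_config(n = 1, signal_separation = 0, noise_sd = 0.1)
  beta0 <- with_seed(6, generate_methylation_profiles(labels, cfg0))
  acc0 <- mean(nearest_centroid_labels(beta0, cfg0) == labels)
  expect_lt(acc0, 0.40)

  # single-profile accessor mirrors the matrix generator
  p <- with_seed(3, generate_methylation_profile("WNT", cfg))
  expect_named(p, c("beta", "probe_chromosomes"))
  expect_length(p$beta, 600)
  expect_identical(unname(p$probe_chromosomes[101]), "chr6")
})

test_that("copy-number tracks reflect amplification and chr6 monosomy", {
  cfg <- quick_config(n = 60, seed = 77)
  co <- generate_cohort(cfg, apply_failures = FALSE)
  lay <- co$layout
  mono <- co$patients$chr6_monosomy
  if (any(mono) && any(!mono)) {
    chr6_means <- colMeans(co$cn_log2[lay$chromosome == "chr6", ])
    auto_means <- colMeans(co$cn_log2[lay$chromosome != "chr6", ])
    expect_true(all(chr6_means[mono] < auto_means[mono] - 0.2))
  }
  amp <- co$patients$mycn_amp
  if (any(amp)) {
    locus_means <- colMeans(co$cn_log2[lay$role == "locus_MYCN", ])
    expect_true(all(locus_means[amp] > 0.5))
    expect_true(all(locus_means[!amp] < 0.5))
  }
})

test_that("failure processes apply at configured rates with reason codes", {
  cfg_none <- quick_config(n = 30, seed = 2,
                           failure_rates = list(low_dna = 0, low_rna = 0,
                                                low_rin = 0, ifish = 0,
                                                mlpa = 0))
  base <- generate_cohort(cfg_none, apply_failures = FALSE)
  same <- apply_failure_processes(base, cfg_none)
  expect_identical(base$specimens, same$specimens)
  expect_identical(base$ifish, same$ifish)
  expect_identical(nrow(same$failures), 0L)

  # all-failing DNA: every specimen below threshold, methylation QC rejects all
  cfg_dna <- quick_config(n = 30, seed = 2,
                          failure_rates = list(low_dna = 1, low_rna = 0,
                                               low_rin = 0, ifish = 0,
                                               mlpa = 0))
  broken <- apply_failure_processes(base, cfg_dna)
  expect_true(all(broken$specimens$dsdna_ng < 500))
  qc <- assess_specimens(broken$specimens)
  expect_false(any(qc$methylation_eligible))
  expect_true(all(grepl("low_dna_yield", qc$reasons)))

  # RIN failure rate ~ 27%: failing RIN fraction within 3 binomial SDs
  cfg_rin <- quick_config(n = 600, seed = 21,
                          failure_rates = list(low_dna = 0, low_rna = 0,
                                               low_rin = 0.27, ifish = 0,
                                               mlpa = 0))
  co <- generate_cohort(cfg_rin)
  frac <- mean(co$specimens$rin <= 5, na.rm = TRUE)
  expect_lt(abs(frac - 0.27), 3 * sqrt(0.27 * 0.73 / 600))
  expect_true(all(co$failures$mode == "low_rin"))
  expect_true(all(co$failures$reason == "low_quality_rna"))
})

test_that("cohort tables round-trip through a directory", {
  cfg <- quick_config(n = 8, seed = 4)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(all(file.exists(files)))
  back <- read_cohort(dir)
  expect_identical(back$patients$patient_id, co$patients$patient_id)
  expect_equal(back$methylation, co$methylation, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$config$seed, co$config$seed)
  expect_equal(back$config$subgroup_priors, co$config$subgroup_priors)
})
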