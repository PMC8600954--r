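test_that("fitting requires a representative training set", {
  cfg <- quick_config()
  labels <- rep(c("WNT", "SHH", "Group3"), each = 8)
  beta <- with_seed(21, generate_methylation_profiles(labels, cfg))
  expect_error(fit_metagenes(beta, labels), "Group4")
  labels2 <- rep(MB_SUBGROUPS, c(3, 10, 10, 10))
  beta2 <- with_seed(22, generate_methylation_profiles(labels2, cfg))
  expect_error(fit_metagenes(beta2, labels2), "WNT")
})

test_that("noiseless archetypes classify correctly with full confidence", {
  model <- small_model()
  cfg <- small_model_config()
  for (sg in MB_SUBGROUPS) {
    call <- classify(archetype_profile(sg, cfg), model)
    expect_identical(call$label, sg)
    expect_identical(call$confidence, 1)
    expect_identical(call$platform, "methylation")
  }
  expect_error(classify(rep(0.5, 10), model), "dimension")
})

test_that("a centroid midpoint is non-classifiable under symmetric training", {
  # Exactly mirror-symmetric scenario: the basis is the true centroid set and
  # the training cohort is invariant under the probe permutation exchanging
  # the WNT and SHH marker blocks (SHH samples are mirrored WNT samples,
  # Group3/4 samples are mirror-invariant). By symmetry the bootstrap votes
  # on the WNT/SHH centroid midpoint split evenly, so the call must be NC.
  cfg <- quick_config()
  centro <- mbdx:::methylation_centroids(cfg)
  layout <- probe_layout(cfg$n_probes)
  sigma <- seq_len(nrow(layout))
  wnt_idx <- which(layout$role == "marker_WNT")
  shh_idx <- which(layout$role == "marker_SHH")
  sigma[wnt_idx] <- shh_idx
  sigma[shh_idx] <- wnt_idx
  W <- sweep(centro, 2, sqrt(colSums(centro^2)), "/")
  n_per <- 12
  set.seed(46)
  noise <- function() matrix(rnorm(nrow(layout) * n_per, 0, 0.08), nrow(layout))
  wnt <- pmin(pmax(centro[, "WNT"] + noise(), 0), 1)
  shh <- wnt[sigma, ]
  sym_noise <- function() { e <- noise(); (e + e[sigma, ]) / 2 }
  g3 <- pmin(pmax(centro[, "Group3"] + sym_noise(), 0), 1)
  g4 <- pmin(pmax(centro[, "Group4"] + sym_noise(), 0), 1)
  x <- cbind(wnt, shh, g3, g4)
  labels <- rep(MB_SUBGROUPS, each = n_per)
  Pn <- mbdx:::unit_rows(t(nnls_project(x, W)))
  colnames(Pn) <- MB_SUBGROUPS
  y <- factor(labels, MB_SUBGROUPS)
  ens <- with_seed(146, lapply(seq_len(400), function(b) {
    repeat {
      idx <- sample(length(labels), replace = TRUE)
      if (length(unique(labels[idx])) == 4) break
    }
    e1071::svm(Pn[idx, ], y[idx], kernel = "linear", cost = 1, scale = FALSE)
  }))
  model <- structure(list(basis = W, ensemble = ens, platform = "methylation"),
                     class = "metagene_model")
  mid <- (centro[, "WNT"] + centro[, "SHH"]) / 2
  call <- classify(mid, model)
  expect_lte(call$confidence, 0.80)
  expect_identical(call$label, "NC")
  # while the archetypes themselves classify with full confidence
  expect_identical(classify(centro[, "WNT"], model)$confidence, 1)
})

test_that("every call satisfies the NC/confidence invariant", {
  model <- small_model()
  cfg <- small_model_config()
  cfg$noise_sd <- 0.35  # noisy enough that some calls fall below threshold
  labels <- with_seed(23, sample(MB_SUBGROUPS, 120, replace = TRUE))
  beta <- with_seed(24, generate_methylation_profiles(labels, cfg))
  res <- classify_cohort(beta, model)
  expect_identical(res$label == "NC", res$confidence < 0.80)
  expect_true(all(res$confidence >= 0 & res$confidence <= 1))
  expect_true(all(res$modal_label %in% MB_SUBGROUPS))
})

test_that("labels are recovered on held-out cohorts at reference separation", {
  model <- small_model()
  cfg <- small_model_config()
  labels <- with_seed(25, sample(MB_SUBGROUPS, 200, replace = TRUE))
  beta <- with_seed(26, generate_methylation_profiles(labels, cfg))
  res <- classify_cohort(beta, model)
  recall <- vapply(MB_SUBGROUPS, function(sg) {
    mean(res$modal_label[labels == sg] == sg)
  }, numeric(1))
  expect_gte(mean(recall), 0.95)
})

test_that("classification is deterministic for a fixed fitted model", {
  model <- small_model()
  cfg <- small_model_config()
  labels <- rep(MB_SUBGROUPS, each = 3)
  beta <- with_seed(27, generate_methylation_profiles(labels, cfg))
  r1 <- classify_cohort(beta, model)
  r2 <- classify_cohort(beta, model)
  expect_identical(r1, r2)
  # refitting with the same seed reproduces the same model behaviour
  m2 <- fit_metagenes(.mbdx_test_cache$beta, .mbdx_test_cache$labels,
                      nmf_seed = 1, n_restarts = 8, n_resamples = 200)
  expect_identical(classify_cohort(beta, m2), r1)
})

test_that("the expression arm mirrors the methylation classifier", {
  cfg <- quick_config()
  labels <- rep(MB_SUBGROUPS, each = 10)
  x <- with_seed(28, generate_expression_profiles(labels, cfg))
  emodel <- fit_metagenes(x, labels, nmf_seed = 5, n_restarts = 8,
                          n_resamples = 200, platform = "rnaseq")
  centroids <- mbdx:::expression_centroids(cfg)
  for (sg in c("WNT", "Group3")) {
    call <- classify_expression(centroids[, sg], emodel)
    expect_identical(call$label, sg)
    expect_identical(call$platform, "rnaseq")
    expect_identical(call$confidence, 1)
  }
  expect_error(classify_expression(centroids[, "WNT"], small_model()),
               "rnaseq")
})
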