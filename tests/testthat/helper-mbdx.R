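# Shared fixtures and independent oracles for the mbdx test suite.
# Everything is generated in code at test time; nothing is read from disk.

# Small, fast cohort configuration for unit tests.
quick_config <- function(n = 40, seed = 42, ...) {
  cohort_config(n_patients = n, n_probes = 600, n_genes = 200, seed = seed, ...)
}

# Fit one small methylation metagene model per session and reuse it across
# tests (balanced 12-per-subgroup training set, reduced restarts/resamples).
.mbdx_test_cache <- new.env(parent = emptyenv())

small_model <- function() {
  if (is.null(.mbdx_test_cache$model)) {
    cfg <- quick_config()
    labels <- rep(MB_SUBGROUPS, each = 12)
    beta <- with_seed(7, generate_methylation_profiles(labels, cfg))
    .mbdx_test_cache$cfg <- cfg
    .mbdx_test_cache$labels <- labels
    .mbdx_test_cache$beta <- beta
    .mbdx_test_cache$model <- fit_metagenes(beta, labels, nmf_seed = 1,
                                            n_restarts = 8, n_resamples = 200)
  }
  .mbdx_test_cache$model
}

small_model_config <- function() {
  small_model()
  .mbdx_test_cache$cfg
}

# Independent nearest-centroid oracle: assign each sample to the subgroup
# whose 50-probe marker block has the highest mean beta. Uses only the probe
# layout, never the NMF/SVM path.
nearest_centroid_labels <- function(beta, config) {
  layout <- probe_layout(config$n_probes)
  block_means <- vapply(MB_SUBGROUPS, function(sg) {
    colMeans(beta[layout$role == paste0("marker_", sg), , drop = FALSE])
  }, numeric(ncol(beta)))
  if (ncol(beta) == 1) block_means <- matrix(block_means, nrow = 1)
  MB_SUBGROUPS[max.col(block_means, ties.method = "first")]
}

# Brute-force WNT consensus oracle: enumerate every completion of the unknown
# fields; the three-valued status is decided when all completions agree.
wnt_consensus_oracle <- function(ctnnb1, measures) {
  full_rule <- function(mut, m) isTRUE(mut) || sum(m) >= 2
  mut_opts <- if (is.na(ctnnb1)) c(TRUE, FALSE) else ctnnb1
  unknown <- which(is.na(measures))
  outcomes <- c()
  fill_grid <- if (length(unknown)) {
    expand.grid(rep(list(c(TRUE, FALSE)), length(unknown)))
  } else {
    data.frame(row.names = 1)
  }
  for (mut in mut_opts) {
    for (g in seq_len(nrow(fill_grid))) {
      m <- measures
      if (length(unknown)) m[unknown] <- unlist(fill_grid[g, ])
      outcomes <- c(outcomes, full_rule(mut, m))
    }
  }
  if (all(outcomes)) "positive" else if (!any(outcomes)) "negative"
  else "indeterminate"
}

# Centroid beta profile for a subgroup (the noiseless archetype).
archetype_profile <- function(subgroup, config) {
  mbdx:::methylation_centroids(config)[, subgroup]
}
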