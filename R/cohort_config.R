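#' Configuration for the synthetic medulloblastoma cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults emulate a national referral cohort of 135
#' patients: subgroup mix dominated by Group4 (36%) and Group3 (24%) with a 10%
#' WNT fraction, subgroup-restricted biomarkers (CTNNB1 mutation and chromosome
#' 6 monosomy in WNT, TP53 mutation and MYCN amplification enriched in SHH, MYC
#' amplification in Group3), right-skewed specimen yields in which ~92% of
#' frozen biopsies exceed 2000 ng dsDNA, an RNA-integrity failure rate of 27%,
#' and log-normal shipping/processing timelines with median surgery-to-receipt
#' of 14 days.
#'
#' @param n_patients number of patients to simulate.
#' @param subgroup_priors named probabilities for WNT, SHH, Group3, Group4;
#'   must sum to 1.
#' @param biomarker_rates named list of per-subgroup Bernoulli rates for
#'   `myc_amp`, `mycn_amp`, `tp53_mut`, `ctnnb1_mut`, `chr6_monosomy`, `lca`.
#'   Each element is a probability vector named by subgroup.
#' @param clinical_rates list with `metastatic` (M+ probability),
#'   `incomplete_resection` (R+ probability), `local_variant_assigned`
#'   (probability a local pathologist commits to a variant),
#'   `local_variant_error` (probability an assigned local variant disagrees
#'   with central review), `central_unresolved` (probability central review
#'   returns MBNOS).
#' @param n_probes number of methylation probes (>= 4 marker blocks plus the
#'   chromosome-6 and MYC/MYCN copy-number loci; minimum 600 under the default
#'   layout).
#' @param n_genes number of expression features.
#' @param signal_separation beta-value offset between a subgroup's marker-block
#'   centroid and background (nonnegative).
#' @param noise_sd standard deviation of the additive Gaussian probe noise
#'   (beta values are clipped to \[0, 1\] after noise).
#' @param failure_rates list of probabilities: `low_dna`, `low_rna`, `low_rin`,
#'   `ifish` (per-patient technical iFISH failure), `mlpa` (per-assay reference
#'   dropout).
#' @param assay_params overrides for the assay error model (see the
#'   `ASSAY_DEFAULTS` source constant): `ifish_background`, `mlpa_spike_rate`,
#'   `mlpa_degradation_rate`, `mlpa_measurement_sd`, `array_amp_range`,
#'   `array_noise_sd`. Setting the rates/noise to zero and the amplitude range
#'   to a fixed high value makes every platform recover ground truth exactly.
#' @param timeline_params list of log-normal `(meanlog, sdlog)` pairs for
#'   `surgery_to_receipt`, `fish_processing`, `fish_reporting`,
#'   `histology_processing`, `cpr_review`, plus `delay_prob`, `delay_reasons`
#'   (named probabilities for personnel / additional_cpr / ihc_repeat) and
#'   `delay_extra` (meanlog, sdlog of the extra days a delay event adds).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 20, seed = 7)
#' cfg$subgroup_priors
cohort_config <- function(n_patients = 135,
                          subgroup_priors = c(WNT = 0.10, SHH = 0.30,
                                              Group3 = 0.24, Group4 = 0.36),
                          biomarker_rates = list(
                            myc_amp       = c(WNT = 0, SHH = 0, Group3 = 0.24, Group4 = 0.02),
                            mycn_amp      = c(WNT = 0, SHH = 0.18, Group3 = 0.03, Group4 = 0.10),
                            tp53_mut      = c(WNT = 0.03, SHH = 0.21, Group3 = 0, Group4 = 0),
                            ctnnb1_mut    = c(WNT = 0.90, SHH = 0, Group3 = 0, Group4 = 0),
                            chr6_monosomy = c(WNT = 0.88, SHH = 0, Group3 = 0, Group4 = 0),
                            lca           = c(WNT = 0.02, SHH = 0.12, Group3 = 0.30, Group4 = 0.10)
                          ),
                          clinical_rates = list(
                            metastatic = 0.22,
                            incomplete_resection = 0.10,
                            local_variant_assigned = 0.78,
                            local_variant_error = 0.10,
                            central_unresolved = 0.05
                          ),
                          n_probes = 1000,
                          n_genes = 400,
                          signal_separation = 0.40,
                          noise_sd = 0.10,
                          failure_rates = list(low_dna = 0.015, low_rna = 0.13,
                                               low_rin = 0.27, ifish = 0.13,
                                               mlpa = 0.07),
                          assay_params = list(),
                          timeline_params = list(
                            surgery_to_receipt   = c(meanlog = log(14), sdlog = 1.04),
                            fish_processing      = c(meanlog = log(4.0), sdlog = 0.60),
                            fish_reporting       = c(meanlog = log(6.0), sdlog = 0.50),
                            histology_processing = c(meanlog = log(5.0), sdlog = 0.55),
                            cpr_review           = c(meanlog = log(8.0), sdlog = 0.55),
                            delay_prob = 0.12,
                            delay_reasons = c(personnel = 0.53,
                                              additional_cpr = 0.33,
                                              ihc_repeat = 0.14),
                            delay_extra = c(meanlog = log(8), sdlog = 0.5)
                          ),
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, subgroup_priors = subgroup_priors,
              biomarker_rates = biomarker_rates, clinical_rates = clinical_rates,
              n_probes = n_probes, n_genes = n_genes,
              signal_separation = signal_separation, noise_sd = noise_sd,
              failure_rates = failure_rates,
              assay_params = utils::modifyList(ASSAY_DEFAULTS, assay_params),
              timeline_params = timeline_params,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1L ||
      cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients)) {
    stop("configuration error: 'n_patients' must be a nonnegative integer",
         call. = FALSE)
  }
  p <- cfg$subgroup_priors
  if (length(p) != 4L || !setequal(names(p), MB_SUBGROUPS)) {
    stop("configuration error: 'subgroup_priors' must be named WNT/SHH/Group3/Group4",
         call. = FALSE)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("configuration error: 'subgroup_priors' must be nonnegative and sum to 1",
         call. = FALSE)
  }
  for (nm in names(cfg$biomarker_rates)) {
    r <- cfg$biomarker_rates[[nm]]
    if (any(r < 0 | r > 1)) {
      stop(sprintf("configuration error: 'biomarker_rates$%s' outside [0,1]", nm),
           call. = FALSE)
    }
  }
  for (nm in names(cfg$failure_rates)) {
    r <- cfg$failure_rates[[nm]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop(sprintf("configuration error: 'failure_rates$%s' outside [0,1]", nm),
           call. = FALSE)
    }
  }
  for (nm in c("metastatic", "incomplete_resection", "local_variant_assigned",
               "local_variant_error", "central_unresolved")) {
    r <- cfg$clinical_rates[[nm]]
    if (is.null(r) || r < 0 || r > 1) {
      stop(sprintf("configuration error: 'clinical_rates$%s' outside [0,1]", nm),
           call. = FALSE)
    }
  }
  for (nm in c("ifish_background", "mlpa_spike_rate", "mlpa_degradation_rate")) {
    r <- cfg$assay_params[[nm]]
    if (!is.numeric(r) || r < 0 || r > 1) {
      stop(sprintf("configuration error: 'assay_params$%s' outside [0,1]", nm),
           call. = FALSE)
    }
  }
  if (cfg$signal_separation < 0) {
    stop("configuration error: 'signal_separation' must be nonnegative", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("configuration error: 'noise_sd' must be nonnegative", call. = FALSE)
  }
  layout <- try(probe_layout(cfg$n_probes), silent = TRUE)
  if (inherits(layout, "try-error")) {
    stop("configuration error: 'n_probes' too small for the probe layout (need >= 600)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  priors:  ", paste(sprintf("%s=%.2f", names(x$subgroup_priors),
                                   x$subgroup_priors), collapse = " "), "\n")
  cat("  probes:", x$n_probes, " genes:", x$n_genes,
      " separation:", x$signal_separation, " noise_sd:", x$noise_sd, "\n")
  invisible(x)
}

#' Read / write cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_patients", "n_probes", "n_genes", "signal_separation",
               "noise_sd", "seed")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$subgroup_priors)) args$subgroup_priors <- unlist(raw$subgroup_priors)
  if (!is.null(raw$biomarker_rates)) {
    args$biomarker_rates <- lapply(raw$biomarker_rates, unlist)
  }
  if (!is.null(raw$clinical_rates)) args$clinical_rates <- raw$clinical_rates
  if (!is.null(raw$failure_rates)) args$failure_rates <- raw$failure_rates
  if (!is.null(raw$assay_params)) {
    ap <- raw$assay_params
    if (!is.null(ap$array_amp_range)) ap$array_amp_range <- unlist(ap$array_amp_range)
    args$assay_params <- ap
  }
  if (!is.null(raw$timeline_params)) {
    tp <- raw$timeline_params
    tp[] <- lapply(tp, function(x) if (is.list(x)) unlist(x) else x)
    args$timeline_params <- tp
  }
  do.call(cohort_config, args)
}

#' @rdname read_cohort_config
#' @param cfg a `cohort_config`.
#' @export
write_cohort_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$subgroup_priors <- as.list(out$subgroup_priors)
  out$biomarker_rates <- lapply(out$biomarker_rates, as.list)
  out$timeline_params <- lapply(out$timeline_params, function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
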