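# Synthetic cohort generator: seeded patients, specimens, molecular profiles,
# raw assay data and timelines with the statistical structure the downstream
# pipeline assumes.

MARKER_BLOCK_SIZE <- 50L

# Assay error-model defaults, calibrated so the three copy-number platforms
# reproduce the qualitative error ordering seen in practice: iFISH near-exact,
# MLPA prone to false positives (technical spikes) and some false negatives
# (signal degradation), methylation-array fully specific but insensitive when
# tumour-content dilution pulls the focal amplitude below the calling
# threshold. Overridable per cohort via cohort_config(assay_params = ...).
ASSAY_DEFAULTS <- list(
  ifish_background = 0.01,       # amplified-looking nuclei in normal tumours
  mlpa_spike_rate = 0.09,        # technical false-positive spikes
  mlpa_degradation_rate = 0.20,  # amplified signal degraded (false negatives)
  mlpa_measurement_sd = 0.15,    # log-scale multiplicative measurement noise
  array_amp_range = c(1, 3),     # focal log2 amplitude range when amplified
  array_noise_sd = 0.10          # per-probe log2 noise
)

#' Probe layout for the simulated methylation array
#'
#' Deterministic probe annotation: four disjoint 50-probe subgroup marker
#' blocks (chr1/chr3/chr4/chr5), a 100-probe chromosome-6 region, 50-probe
#' MYC (chr8) and MYCN (chr2) copy-number loci, and background probes cycled
#' over the remaining autosomes in 50-probe runs. Copy-number binning operates
#' within chromosomes, so each locus occupies exactly one 50-probe bin.
#'
#' @param n_probes total probe count (>= 600).
#' @return data.frame with `probe_id`, `chromosome`, `role` (one of `none`,
#'   `marker_WNT`, `marker_SHH`, `marker_Group3`, `marker_Group4`,
#'   `locus_MYC`, `locus_MYCN`).
#' @export
probe_layout <- function(n_probes) {
  if (n_probes < 600) stop("n_probes must be >= 600", call. = FALSE)
  chromosome <- character(n_probes)
  role <- rep("none", n_probes)
  chromosome[1:100] <- "chr2";  role[51:100]  <- "locus_MYCN"
  chromosome[101:200] <- "chr6"
  chromosome[201:300] <- "chr8"; role[251:300] <- "locus_MYC"
  blocks <- list(marker_WNT = 301:350, marker_SHH = 351:400,
                 marker_Group3 = 401:450, marker_Group4 = 451:500)
  marker_chrs <- c("chr1", "chr3", "chr4", "chr5")
  for (i in seq_along(blocks)) {
    chromosome[blocks[[i]]] <- marker_chrs[i]
    role[blocks[[i]]] <- names(blocks)[i]
  }
  filler <- setdiff(paste0("chr", 1:22),
                    c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chr8"))
  idx <- 501:n_probes
  run <- (seq_along(idx) - 1) %/% MARKER_BLOCK_SIZE
  chromosome[idx] <- filler[(run %% length(filler)) + 1]
  data.frame(probe_id = sprintf("cg%05d", seq_len(n_probes)),
             chromosome = chromosome, role = role,
             stringsAsFactors = FALSE)
}

# Subgroup centroids on the beta scale: background 0.2, own marker block
# elevated by signal_separation. Returns probes x 4 matrix.
methylation_centroids <- function(config, layout = probe_layout(config$n_probes)) {
  centroids <- matrix(0.2, nrow = nrow(layout), ncol = 4,
                      dimnames = list(layout$probe_id, MB_SUBGROUPS))
  for (sg in MB_SUBGROUPS) {
    centroids[layout$role == paste0("marker_", sg), sg] <-
      0.2 + config$signal_separation
  }
  centroids
}

expression_centroids <- function(config) {
  n <- config$n_genes
  block <- max(10L, n %/% 10L)
  centroids <- matrix(1, nrow = n, ncol = 4,
                      dimnames = list(sprintf("gene%04d", seq_len(n)), MB_SUBGROUPS))
  for (i in seq_along(MB_SUBGROUPS)) {
    rows <- ((i - 1) * block + 1):(i * block)
    centroids[rows, MB_SUBGROUPS[i]] <- 1 + 5 * config$signal_separation
  }
  centroids
}

#' Simulate methylation profiles for given subgroups
#'
#' Beta values are the subgroup centroid plus additive Gaussian noise, clipped
#' to \[0, 1\]. Used internally by [generate_cohort()]; exposed so the profile
#' model can be studied in isolation.
#'
#' @param subgroups character vector of subgroup labels (one per profile).
#' @param config a [cohort_config()].
#' @return probes x length(subgroups) matrix of beta values with the probe
#'   layout attached as attribute `layout`.
#' @export
generate_methylation_profiles <- function(subgroups, config) {
  bad <- setdiff(unique(subgroups), MB_SUBGROUPS)
  if (length(bad)) {
    stop("unknown subgroup label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  layout <- probe_layout(config$n_probes)
  centroids <- methylation_centroids(config, layout)
  n <- length(subgroups)
  beta <- centroids[, subgroups, drop = FALSE] +
    matrix(stats::rnorm(nrow(layout) * n, 0, config$noise_sd), nrow = nrow(layout))
  beta <- pmin(pmax(beta, 0), 1)
  colnames(beta) <- if (n) sprintf("S%04d", seq_len(n)) else NULL
  attr(beta, "layout") <- layout
  beta
}

#' @rdname generate_methylation_profiles
#' @param subgroup a single subgroup label.
#' @return `generate_methylation_profile()` returns a list with `beta` (named
#'   vector) and `probe_chromosomes` (named chromosome labels).
#' @export
generate_methylation_profile <- function(subgroup, config) {
  m <- generate_methylation_profiles(subgroup, config)
  layout <- attr(m, "layout")
  list(beta = stats::setNames(m[, 1], layout$probe_id),
       probe_chromosomes = stats::setNames(layout$chromosome, layout$probe_id))
}

#' Simulate expression profiles for given subgroups
#'
#' Nonnegative abundances with the same disjoint block structure as the
#' methylation model, on an arbitrary abundance scale.
#'
#' @inheritParams generate_methylation_profiles
#' @return genes x length(subgroups) nonnegative matrix.
#' @export
generate_expression_profiles <- function(subgroups, config) {
  bad <- setdiff(unique(subgroups), MB_SUBGROUPS)
  if (length(bad)) {
    stop("unknown subgroup label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  centroids <- expression_centroids(config)
  n <- length(subgroups)
  x <- centroids[, subgroups, drop = FALSE] +
    matrix(stats::rnorm(config$n_genes * n, 0, 5 * config$noise_sd),
           nrow = config$n_genes)
  x <- pmax(x, 0)
  colnames(x) <- if (n) sprintf("S%04d", seq_len(n)) else NULL
  x
}

# Copy-number log2-ratio tracks (probes x n). Amplified patients carry a
# focal gain over the 50-probe target locus with amplitude drawn from
# assay$array_amp_range (tumour-content dilution: draws below the focal
# calling threshold are the platform's false negatives); chromosome-6
# monosomy shifts all chr6 probes by -0.5.
generate_cn_tracks <- function(patients, layout, assay = ASSAY_DEFAULTS) {
  n <- nrow(patients)
  cn <- matrix(stats::rnorm(nrow(layout) * n, 0, assay$array_noise_sd),
               nrow = nrow(layout),
               dimnames = list(layout$probe_id, patients$patient_id))
  if (n == 0) return(cn)
  amp_myc <- stats::runif(n, assay$array_amp_range[1], assay$array_amp_range[2])
  amp_mycn <- stats::runif(n, assay$array_amp_range[1], assay$array_amp_range[2])
  for (i in seq_len(n)) {
    if (patients$myc_amp[i])  cn[layout$role == "locus_MYC", i]  <-
        cn[layout$role == "locus_MYC", i] + amp_myc[i]
    if (patients$mycn_amp[i]) cn[layout$role == "locus_MYCN", i] <-
        cn[layout$role == "locus_MYCN", i] + amp_mycn[i]
    if (patients$chr6_monosomy[i]) cn[layout$chromosome == "chr6", i] <-
        cn[layout$chromosome == "chr6", i] - 0.5
  }
  cn
}

draw_variant <- function(subgroup, lca) {
  n <- length(subgroup)
  out <- character(n)
  for (i in seq_len(n)) {
    if (lca[i]) {
      out[i] <- "LCA"
    } else if (subgroup[i] == "SHH") {
      out[i] <- sample(c("CLA", "DN", "MBEN"), 1, prob = c(0.60, 0.35, 0.05))
    } else {
      out[i] <- sample(c("CLA", "DN"), 1, prob = c(0.95, 0.05))
    }
  }
  out
}

# Nuclear beta-catenin IHC percentage: WNT cases draw from a high-positivity
# mixture (with a sub-threshold tail so false negatives occur), non-WNT from a
# low mixture with a small false-positive component.
draw_ihc_pct <- function(is_wnt) {
  n <- length(is_wnt)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is_wnt[i]) {
      out[i] <- if (stats::runif(1) < 0.75) stats::runif(1, 15, 95)
                else stats::runif(1, 0, 9.9)
    } else {
      u <- stats::runif(1)
      out[i] <- if (u < 0.02) stats::runif(1, 10, 25)
                else if (u < 0.10) stats::runif(1, 3, 9.9)
                else stats::runif(1, 0, 3)
    }
  }
  out
}

draw_timelines <- function(n, tp) {
  ln <- function(p, n) stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]])
  surgery <- ln(tp$surgery_to_receipt, n)
  fish_p <- ln(tp$fish_processing, n)
  fish_r <- ln(tp$fish_reporting, n)
  hist_p <- ln(tp$histology_processing, n)
  cpr <- ln(tp$cpr_review, n)
  delayed <- stats::runif(n) < tp$delay_prob
  reason <- rep("none", n)
  extra <- numeric(n)
  if (any(delayed)) {
    reason[delayed] <- sample(names(tp$delay_reasons), sum(delayed),
                              replace = TRUE, prob = tp$delay_reasons)
    extra[delayed] <- ln(tp$delay_extra, sum(delayed))
  }
  data.frame(
    surgery_to_receipt_days = surgery,
    fish_processing_days = fish_p,
    fish_reporting_days = fish_r,
    histology_processing_days = hist_p,
    cpr_review_days = cpr,
    receipt_to_report_days = pmax(fish_p + fish_r, hist_p + cpr) + extra,
    delay_reason = reason,
    stringsAsFactors = FALSE
  )
}

# Per-nucleus iFISH signal counts, one assay per patient and target.
# Amplified tumours carry a clonal fraction of nuclei with high target
# counts; normal tumours a small background of amplified-looking nuclei.
draw_ifish <- function(patients, assay = ASSAY_DEFAULTS) {
  n <- nrow(patients)
  if (n == 0) {
    return(data.frame(patient_id = character(), target = character(),
                      nucleus = integer(), target_signals = integer(),
                      control_signals = integer(), stringsAsFactors = FALSE))
  }
  target_lab <- rep(c("MYC", "MYCN"), each = n)
  amp <- c(patients$myc_amp, patients$mycn_amp)
  n_nuc <- 60L + stats::rpois(2L * n, 40)
  frac <- ifelse(amp, stats::runif(2L * n, 0.3, 0.9), assay$ifish_background)
  total <- sum(n_nuc)
  control <- sample(1:3, total, replace = TRUE)
  target_sig <- sample(1:3, total, replace = TRUE)
  hot <- stats::runif(total) < rep(frac, n_nuc)
  target_sig[hot] <- sample(12:40, sum(hot), replace = TRUE)
  data.frame(patient_id = rep(rep(patients$patient_id, 2L), n_nuc),
             target = rep(target_lab, n_nuc),
             nucleus = sequence(n_nuc),
             target_signals = target_sig, control_signals = control,
             stringsAsFactors = FALSE)
}

# MLPA raw signals: target probe plus four reference loci. Amplified tumours
# have high dosage ratios occasionally degraded below the calling cut-off
# (false negatives); normal tumours carry an occasional technical spike
# (false positives) - MLPA is the noisiest of the three platforms.
draw_mlpa <- function(patients, assay = ASSAY_DEFAULTS) {
  n <- nrow(patients)
  if (n == 0) {
    return(data.frame(patient_id = character(), target = character(),
                      target_signal = numeric(), ref_b2m = numeric(),
                      ref_tbp = numeric(), ref_7q31 = numeric(),
                      ref_14q22 = numeric(), stringsAsFactors = FALSE))
  }
  out <- list()
  for (tg in c("MYC", "MYCN")) {
    amp <- if (tg == "MYC") patients$myc_amp else patients$mycn_amp
    ratio <- rep(1, n)
    ratio[amp] <- stats::runif(sum(amp), 5, 12)
    degraded <- amp & stats::runif(n) < assay$mlpa_degradation_rate
    ratio[degraded] <- ratio[degraded] * stats::runif(sum(degraded), 0.1, 0.35)
    spiked <- !amp & stats::runif(n) < assay$mlpa_spike_rate
    ratio[spiked] <- ratio[spiked] * stats::runif(sum(spiked), 2.8, 6)
    refs <- matrix(stats::rlnorm(4 * n, 0, 0.08), ncol = 4)
    target_signal <- ratio * rowMeans(refs) *
      exp(stats::rnorm(n, 0, assay$mlpa_measurement_sd))
    out[[tg]] <- data.frame(
      patient_id = patients$patient_id, target = tg,
      target_signal = target_signal,
      ref_b2m = refs[, 1], ref_tbp = refs[, 2],
      ref_7q31 = refs[, 3], ref_14q22 = refs[, 4],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Generate a seeded synthetic cohort
#'
#' Draws a full synthetic referral cohort: per-patient ground-truth biology and
#' clinical covariates, specimen metrics, methylation/expression matrices,
#' copy-number log2 tracks, raw iFISH and MLPA assay data, and
#' submission/processing timelines. Deterministic for a fixed configuration
#' (including its seed). When `apply_failures = TRUE` (default) the stochastic
#' assay-failure processes of [apply_failure_processes()] are applied before
#' returning.
#'
#' @param config a [cohort_config()].
#' @param apply_failures apply the configured failure processes.
#' @return an object of class `mb_cohort`: a list with elements `config`,
#'   `patients`, `specimens`, `timelines`, `layout`, `methylation`,
#'   `cn_log2`, `expression`, `ifish`, `mlpa`, `failures`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 12, seed = 3))
#' table(cohort$patients$true_subgroup)
generate_cohort <- function(config, apply_failures = TRUE) {
  validate_cohort_config(config)
  n <- config$n_patients
  layout <- probe_layout(config$n_probes)
  cohort <- with_seed(config$seed, {
    subgroup <- if (n) sample(MB_SUBGROUPS, n, replace = TRUE,
                              prob = config$subgroup_priors[MB_SUBGROUPS])
                else character()
    rate_of <- function(field) {
      r <- config$biomarker_rates[[field]][subgroup]
      ifelse(is.na(r), 0, r)
    }
    myc_amp <- stats::runif(n) < rate_of("myc_amp")
    mycn_amp <- !myc_amp & stats::runif(n) < rate_of("mycn_amp")
    tp53_mut <- stats::runif(n) < rate_of("tp53_mut")
    ctnnb1_mut <- stats::runif(n) < rate_of("ctnnb1_mut")
    chr6_monosomy <- stats::runif(n) < rate_of("chr6_monosomy")
    lca <- stats::runif(n) < rate_of("lca")
    true_variant <- draw_variant(subgroup, lca)
    cr <- config$clinical_rates
    central_variant <- ifelse(stats::runif(n) < cr$central_unresolved,
                              "MBNOS", true_variant)
    local_assigned <- stats::runif(n) < cr$local_variant_assigned
    local_variant <- rep("unassigned", n)
    for (i in seq_len(n)) {
      if (local_assigned[i]) {
        local_variant[i] <- if (stats::runif(1) < cr$local_variant_error) {
          sample(setdiff(MB_VARIANTS, true_variant[i]), 1)
        } else true_variant[i]
      }
    }
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age_years = stats::rlnorm(n, log(7.6), 0.70),
      metastatic = stats::runif(n) < cr$metastatic,
      incomplete_resection = stats::runif(n) < cr$incomplete_resection,
      true_subgroup = subgroup, true_variant = true_variant,
      local_variant = local_variant, central_variant = central_variant,
      ctnnb1_mut = ctnnb1_mut, tp53_mut = tp53_mut,
      myc_amp = myc_amp, mycn_amp = mycn_amp,
      chr6_monosomy = chr6_monosomy,
      ihc_nuclear_pct = draw_ihc_pct(subgroup == "WNT"),
      stringsAsFactors = FALSE)
    specimens <- data.frame(
      patient_id = patients$patient_id,
      dsdna_ng = pmax(stats::rlnorm(n, 9.44, 1.31), stats::runif(n, 2100, 2500)),
      dna_volume_ul = stats::runif(n, 25, 42),
      rna_ng = pmax(stats::rlnorm(n, 8.44, 1.20), stats::runif(n, 850, 1000)),
      rin = pmin(pmax(stats::rnorm(n, 7.5, 1.2), 5.2), 10),
      tumour_cell_pct = 60 + 40 * stats::rbeta(n, 2.8, 1.2),
      tissue_remaining = stats::runif(n) < 0.73,
      stringsAsFactors = FALSE)
    timelines <- cbind(data.frame(patient_id = patients$patient_id,
                                  stringsAsFactors = FALSE),
                       draw_timelines(n, config$timeline_params))
    methylation <- generate_methylation_profiles(subgroup, config)
    colnames(methylation) <- patients$patient_id
    expression <- generate_expression_profiles(subgroup, config)
    colnames(expression) <- patients$patient_id
    cn_log2 <- generate_cn_tracks(patients, layout, config$assay_params)
    structure(list(config = config, patients = patients, specimens = specimens,
                   timelines = timelines, layout = layout,
                   methylation = methylation, cn_log2 = cn_log2,
                   expression = expression,
                   ifish = draw_ifish(patients, config$assay_params),
                   mlpa = draw_mlpa(patients, config$assay_params),
                   failures = data.frame(patient_id = character(),
                                         mode = character(),
                                         reason = character(),
                                         stringsAsFactors = FALSE)),
              class = "mb_cohort")
  })
  if (apply_failures) cohort <- apply_failure_processes(cohort, config)
  cohort
}

#' Apply stochastic assay-failure processes to a cohort
#'
#' Each failure mode is applied independently per patient at its configured
#' rate: `low_dna` degrades dsDNA yield below the methylation-array threshold,
#' `low_rna` degrades RNA yield below the RNA-seq threshold, `low_rin` draws a
#' failing RNA integrity number, `ifish` reduces the number of scorable nuclei
#' below the minimum, and `mlpa` zeroes one reference locus. Failures are
#' recorded in `cohort$failures` with a reason code. Deterministic for a fixed
#' configuration seed (a distinct stream from cohort generation).
#'
#' @param cohort an `mb_cohort`.
#' @param config a [cohort_config()]; defaults to the cohort's own.
#' @return the modified `mb_cohort`.
#' @export
apply_failure_processes <- function(cohort, config = cohort$config) {
  n <- nrow(cohort$patients)
  if (n == 0) return(cohort)
  fr <- config$failure_rates
  with_seed(config$seed + 1L, {
    ids <- cohort$patients$patient_id
    fail <- list(
      low_dna = stats::runif(n) < fr$low_dna,
      low_rna = stats::runif(n) < fr$low_rna,
      low_rin = stats::runif(n) < fr$low_rin,
      ifish = stats::runif(n) < fr$ifish
    )
    mlpa_fail <- stats::runif(2 * n) < (fr$mlpa %||% 0)
    recs <- list(cohort$failures)
    if (any(fail$low_dna)) {
      cohort$specimens$dsdna_ng[fail$low_dna] <-
        stats::runif(sum(fail$low_dna), 50, 480)
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = ids[fail$low_dna], mode = "low_dna",
        reason = "poor_dna_yield", stringsAsFactors = FALSE)
    }
    if (any(fail$low_rna)) {
      idx_rna <- which(fail$low_rna)
      rna <- stats::runif(length(idx_rna), 0, 780)
      cohort$specimens$rna_ng[idx_rna] <- rna
      cohort$specimens$rin[idx_rna[rna < 100]] <- NA_real_
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = ids[fail$low_rna], mode = "low_rna",
        reason = ifelse(rna < 100, "insufficient_tissue", "poor_rna_yield"),
        stringsAsFactors = FALSE)
    }
    if (any(fail$low_rin)) {
      keep <- fail$low_rin & !is.na(cohort$specimens$rin)
      cohort$specimens$rin[keep] <- stats::runif(sum(keep), 1.5, 5)
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = ids[fail$low_rin], mode = "low_rin",
        reason = "low_quality_rna", stringsAsFactors = FALSE)
    }
    if (any(fail$ifish)) {
      keep_n <- sample(15:49, sum(fail$ifish), replace = TRUE)
      names(keep_n) <- ids[fail$ifish]
      keep_rows <- rep(TRUE, nrow(cohort$ifish))
      for (id in ids[fail$ifish]) {
        for (tg in c("MYC", "MYCN")) {
          rows <- which(cohort$ifish$patient_id == id & cohort$ifish$target == tg)
          if (length(rows) > keep_n[[id]]) {
            keep_rows[rows[-seq_len(keep_n[[id]])]] <- FALSE
          }
        }
      }
      cohort$ifish <- cohort$ifish[keep_rows, , drop = FALSE]
      rownames(cohort$ifish) <- NULL
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = ids[fail$ifish], mode = "ifish",
        reason = "insufficient_nuclei", stringsAsFactors = FALSE)
    }
    if (any(mlpa_fail) && nrow(cohort$mlpa)) {
      idx <- which(mlpa_fail[seq_len(nrow(cohort$mlpa))])
      cohort$mlpa$ref_tbp[idx] <- 0
      recs[[length(recs) + 1]] <- data.frame(
        patient_id = cohort$mlpa$patient_id[idx], mode = "mlpa",
        reason = "reference_probe_failure", stringsAsFactors = FALSE)
    }
    cohort$failures <- do.call(rbind, recs)
    rownames(cohort$failures) <- NULL
    cohort
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort back from a directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort tables and `config.yaml`.
#' @return an `mb_cohort`.
#' @export
read_cohort <- function(dir) {
  f <- function(x) file.path(dir, x)
  config <- read_cohort_config(f("config.yaml"))
  rd <- function(x) utils::read.csv(f(x), stringsAsFactors = FALSE)
  meth <- utils::read.table(f("methylation.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  layout <- meth[, c("probe_id", "chromosome", "role")]
  methylation <- as.matrix(meth[, -(1:3), drop = FALSE])
  rownames(methylation) <- layout$probe_id
  cn <- utils::read.table(f("cn_log2.tsv"), sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  cn_log2 <- as.matrix(cn[, -(1:3), drop = FALSE])
  rownames(cn_log2) <- layout$probe_id
  expr <- utils::read.table(f("expression.tsv"), sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  expression <- as.matrix(expr[, -1, drop = FALSE])
  rownames(expression) <- expr$gene_id
  structure(list(config = config, patients = rd("cohort.csv"),
                 specimens = rd("specimens.csv"),
                 timelines = rd("timelines.csv"), layout = layout,
                 methylation = methylation, cn_log2 = cn_log2,
                 expression = expression, ifish = rd("ifish.csv"),
                 mlpa = rd("mlpa.csv"), failures = rd("failures.csv")),
            class = "mb_cohort")
}

#' @export
print.mb_cohort <- function(x, ...) {
  cat("<mb_cohort>", nrow(x$patients), "patients,",
      nrow(x$methylation), "probes,", nrow(x$expression), "genes\n")
  if (nrow(x$patients)) print(table(x$patients$true_subgroup))
  invisible(x)
}

#' Write cohort tables to a directory
#'
#' Writes `cohort.csv`, `specimens.csv`, `timelines.csv`, `methylation.tsv`
#' (probes x samples beta matrix with probe annotation columns),
#' `cn_log2.tsv`, `expression.tsv`, `ifish.csv`, `mlpa.csv`, `failures.csv`
#' and `config.yaml`.
#'
#' @param cohort an `mb_cohort`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named character vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(dir, x)
  utils::write.csv(cohort$patients, f("cohort.csv"), row.names = FALSE)
  utils::write.csv(cohort$specimens, f("specimens.csv"), row.names = FALSE)
  utils::write.csv(cohort$timelines, f("timelines.csv"), row.names = FALSE)
  meth <- cbind(cohort$layout, as.data.frame(cohort$methylation))
  utils::write.table(meth, f("methylation.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  cn <- cbind(cohort$layout, as.data.frame(cohort$cn_log2))
  utils::write.table(cn, f("cn_log2.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expr <- cbind(data.frame(gene_id = rownames(cohort$expression)),
                as.data.frame(cohort$expression))
  utils::write.table(expr, f("expression.tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(cohort$ifish, f("ifish.csv"), row.names = FALSE)
  utils::write.csv(cohort$mlpa, f("mlpa.csv"), row.names = FALSE)
  utils::write.csv(cohort$failures, f("failures.csv"), row.names = FALSE)
  write_cohort_config(cohort$config, f("config.yaml"))
  files <- c(cohort = f("cohort.csv"), specimens = f("specimens.csv"),
             timelines = f("timelines.csv"), methylation = f("methylation.tsv"),
             cn_log2 = f("cn_log2.tsv"), expression = f("expression.tsv"),
             ifish = f("ifish.csv"), mlpa = f("mlpa.csv"),
             failures = f("failures.csv"), config = f("config.yaml"))
  invisible(files)
}
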