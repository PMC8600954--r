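# MYC/MYCN amplification calling on three platforms and chromosome-6 monosomy.
# Thresholds are module constants, overridable per call.

IFISH_DEFAULTS <- list(ratio_amplified = 4, signals_amplified = 10,
                       min_nuclei = 50L, pct_amplified = 5)
MLPA_DEFAULTS <- list(amplified_ratio = 3.0, gain_ratio = 1.3)
ARRAY_DEFAULTS <- list(bin_size = 50L, focal_log2 = 1.5,
                       monosomy_log2 = -0.3, neutral_band = 0.1)

#' Score an interphase FISH assay
#'
#' A nucleus is amplified when its target:control signal ratio is at least
#' `ratio_amplified` or its target signal count is at least
#' `signals_amplified`. Nuclei with zero control signals are excluded from
#' scoring. The sample is `amplified` when at least `pct_amplified`% of at
#' least `min_nuclei` scorable nuclei are amplified; with fewer scorable
#' nuclei the assay fails.
#'
#' @param nuclei data.frame with `target_signals` and `control_signals`
#'   (one row per nucleus; at least one nucleus).
#' @param target `"MYC"` or `"MYCN"`.
#' @param thresholds list overriding any of `ratio_amplified`,
#'   `signals_amplified`, `min_nuclei`, `pct_amplified`.
#' @return list of class `ifish_result`: `target`, `status` (`amplified`,
#'   `not_amplified`, `fail`), `nuclei_scored`, `amplified_nuclei_pct`,
#'   `nuclei_excluded`.
#' @export
#' @examples
#' nuc <- data.frame(target_signals = c(20, 2, 2), control_signals = c(2, 2, 2))
#' score_ifish(rbind(nuc[rep(1, 40), ], nuc[rep(2, 60), ]), "MYC")
score_ifish <- function(nuclei, target = c("MYC", "MYCN"), thresholds = list()) {
  target <- match.arg(target)
  th <- utils::modifyList(IFISH_DEFAULTS, thresholds)
  if (!is.data.frame(nuclei) || nrow(nuclei) < 1) {
    stop("score_ifish() requires at least one nucleus", call. = FALSE)
  }
  excluded <- nuclei$control_signals == 0
  nuc <- nuclei[!excluded, , drop = FALSE]
  scored <- nrow(nuc)
  if (scored < th$min_nuclei) {
    return(structure(list(target = target, status = "fail",
                          nuclei_scored = scored,
                          amplified_nuclei_pct = NA_real_,
                          nuclei_excluded = sum(excluded)),
                     class = "ifish_result"))
  }
  amp_nuc <- nuc$target_signals / nuc$control_signals >= th$ratio_amplified |
    nuc$target_signals >= th$signals_amplified
  pct <- 100 * sum(amp_nuc) / scored
  structure(list(target = target,
                 status = if (pct >= th$pct_amplified) "amplified" else "not_amplified",
                 nuclei_scored = scored, amplified_nuclei_pct = pct,
                 nuclei_excluded = sum(excluded)),
            class = "ifish_result")
}

#' Call copy number from MLPA probe signals
#'
#' The dosage ratio is the target-probe signal divided by the mean of the four
#' reference-locus signals. Ratios above `amplified_ratio` are called
#' amplified; ratios in (`gain_ratio`, `amplified_ratio`] are reported as
#' `gain` (not amplification). A missing or non-positive reference locus fails
#' the assay.
#'
#' @param target_signal target-probe signal (nonnegative).
#' @param reference_signals numeric vector of the four reference-locus signals.
#' @param target `"MYC"` or `"MYCN"`.
#' @param thresholds list overriding `amplified_ratio` / `gain_ratio`.
#' @return list of class `mlpa_result`: `target`, `status` (`amplified`,
#'   `gain`, `not_amplified`, `fail`), `target_ratio`, `reason` (for fails).
#' @export
#' @examples
#' call_mlpa(10, c(1, 1, 1, 1), "MYCN")
call_mlpa <- function(target_signal, reference_signals, target = c("MYC", "MYCN"),
                      thresholds = list()) {
  target <- match.arg(target)
  th <- utils::modifyList(MLPA_DEFAULTS, thresholds)
  if (length(reference_signals) != 4 || anyNA(reference_signals) ||
      any(reference_signals <= 0)) {
    return(structure(list(target = target, status = "fail",
                          target_ratio = NA_real_,
                          reason = "missing_or_nonpositive_reference"),
                     class = "mlpa_result"))
  }
  assert_scalar_number(target_signal, "target_signal")
  ratio <- target_signal / mean(reference_signals)
  status <- if (ratio > th$amplified_ratio) "amplified"
            else if (ratio > th$gain_ratio) "gain"
            else "not_amplified"
  structure(list(target = target, status = status, target_ratio = ratio,
                 reason = NA_character_),
            class = "mlpa_result")
}

#' Call copy number from a methylation-array log2-ratio track
#'
#' Probes are segmented into fixed bins of `bin_size` consecutive probes
#' within each chromosome. Focal MYC/MYCN amplification is called when any bin
#' overlapping the locus has mean log2 ratio at or above `focal_log2`.
#' Chromosome-6 monosomy is called when the median chr6 log2 ratio is at or
#' below `monosomy_log2` while the median of all other autosomes lies in the
#' neutral band.
#'
#' @param log2_track numeric vector of per-probe log2 ratios.
#' @param layout probe annotation data.frame as from [probe_layout()]
#'   (`chromosome` and `role` columns aligned with `log2_track`).
#' @param thresholds list overriding `bin_size`, `focal_log2`,
#'   `monosomy_log2`, `neutral_band`.
#' @return list of class `array_cn_result`: `focal_amp_myc`,
#'   `focal_amp_mycn`, `chr6_monosomy` flags, `segments` data.frame
#'   (`chromosome`, `bin`, `n_probes`, `mean_log2`, `overlaps_myc`,
#'   `overlaps_mycn`), `chr6_median`, `autosomal_median`.
#' @export
call_array_cn <- function(log2_track, layout, thresholds = list()) {
  th <- utils::modifyList(ARRAY_DEFAULTS, thresholds)
  if (length(log2_track) != nrow(layout)) {
    stop("log2 track length does not match probe annotation", call. = FALSE)
  }
  for (locus in c("locus_MYC", "locus_MYCN")) {
    if (!any(layout$role == locus)) {
      stop("probe annotation lacks ", sub("locus_", "", locus), " locus",
           call. = FALSE)
    }
  }
  if (!any(layout$chromosome == "chr6")) {
    stop("probe annotation lacks chr6 probes", call. = FALSE)
  }
  segs <- list()
  for (chr in unique(layout$chromosome)) {
    idx <- which(layout$chromosome == chr)
    bin <- (seq_along(idx) - 1L) %/% th$bin_size
    for (b in unique(bin)) {
      rows <- idx[bin == b]
      segs[[length(segs) + 1]] <- data.frame(
        chromosome = chr, bin = b + 1L, n_probes = length(rows),
        mean_log2 = mean(log2_track[rows]),
        overlaps_myc = any(layout$role[rows] == "locus_MYC"),
        overlaps_mycn = any(layout$role[rows] == "locus_MYCN"),
        stringsAsFactors = FALSE)
    }
  }
  segments <- do.call(rbind, segs)
  chr6_median <- stats::median(log2_track[layout$chromosome == "chr6"])
  autosomal_median <- stats::median(log2_track[layout$chromosome != "chr6"])
  structure(list(
    focal_amp_myc = any(segments$overlaps_myc &
                          segments$mean_log2 >= th$focal_log2),
    focal_amp_mycn = any(segments$overlaps_mycn &
                           segments$mean_log2 >= th$focal_log2),
    chr6_monosomy = chr6_median <= th$monosomy_log2 &&
      abs(autosomal_median) <= th$neutral_band,
    segments = segments, chr6_median = chr6_median,
    autosomal_median = autosomal_median),
    class = "array_cn_result")
}

#' Copy-number calls for a whole cohort, all platforms
#'
#' Runs [score_ifish()] and [call_mlpa()] on the cohort's raw assay tables and
#' [call_array_cn()] on each patient's log2 track.
#'
#' @param cohort an `mb_cohort`.
#' @return data.frame with columns `patient_id`, `platform` (`ifish`, `mlpa`,
#'   `array`), `target` (`MYC`, `MYCN`, `chr6`), `status`, `value`
#'   (amplified-nuclei % for iFISH, dosage ratio for MLPA, locus-bin max mean
#'   log2 or chr6 median for the array).
#' @export
call_cohort_cn <- function(cohort) {
  out <- list()
  ifish_by <- split(cohort$ifish,
                    paste(cohort$ifish$patient_id, cohort$ifish$target))
  mlpa_by <- split(cohort$mlpa,
                   paste(cohort$mlpa$patient_id, cohort$mlpa$target))
  for (id in cohort$patients$patient_id) {
    for (tg in c("MYC", "MYCN")) {
      key <- paste(id, tg)
      nuc <- ifish_by[[key]]
      if (!is.null(nuc) && nrow(nuc)) {
        r <- score_ifish(nuc, tg)
        out[[length(out) + 1]] <- data.frame(
          patient_id = id, platform = "ifish", target = tg, status = r$status,
          value = r$amplified_nuclei_pct, stringsAsFactors = FALSE)
      }
      ml <- mlpa_by[[key]]
      if (!is.null(ml) && nrow(ml)) {
        r <- call_mlpa(ml$target_signal[1],
                       c(ml$ref_b2m[1], ml$ref_tbp[1], ml$ref_7q31[1],
                         ml$ref_14q22[1]), tg)
        out[[length(out) + 1]] <- data.frame(
          patient_id = id, platform = "mlpa", target = tg, status = r$status,
          value = r$target_ratio, stringsAsFactors = FALSE)
      }
    }
    arr <- call_array_cn(cohort$cn_log2[, id], cohort$layout)
    myc_bins <- arr$segments$mean_log2[arr$segments$overlaps_myc]
    mycn_bins <- arr$segments$mean_log2[arr$segments$overlaps_mycn]
    out[[length(out) + 1]] <- data.frame(
      patient_id = id, platform = "array", target = c("MYC", "MYCN", "chr6"),
      status = c(ifelse(arr$focal_amp_myc, "amplified", "not_amplified"),
                 ifelse(arr$focal_amp_mycn, "amplified", "not_amplified"),
                 ifelse(arr$chr6_monosomy, "monosomy", "neutral")),
      value = c(max(myc_bins), max(mycn_bins), arr$chr6_median),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(patient_id = character(), platform = character(),
                      target = character(), status = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
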