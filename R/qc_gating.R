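# Specimen-sufficiency gates deciding which assays each specimen may enter.
# All thresholds are strict inequalities: a specimen exactly at a threshold
# fails. Tumour content uses >= 60%.

QC_THRESHOLDS <- list(dsdna_ng = 500, dna_volume_ul = 45, full_panel_ng = 2000,
                      rna_ng = 800, rin = 5, tumour_cell_pct = 60)

#' Assess one specimen against the diagnostic QC gates
#'
#' Eligibility rules: methylation-array requires > 500 ng dsDNA in < 45 ul;
#' RNA-seq requires > 800 ng RNA with RIN > 5 (a missing RIN fails with its
#' own reason code); the full diagnostic/research panel requires > 2000 ng
#' dsDNA; tumour-cell content must be >= 60%.
#'
#' @param specimen a list or one-row data.frame with `dsdna_ng`,
#'   `dna_volume_ul`, `rna_ng`, `rin` (may be `NA`), `tumour_cell_pct`.
#' @return a list of class `qc_decision`: logical flags
#'   `methylation_eligible`, `rnaseq_eligible`, `full_panel_eligible`,
#'   `tumour_content_ok` and a character vector `reasons` explaining every
#'   `FALSE` flag.
#' @export
#' @examples
#' assess_specimen(list(dsdna_ng = 600, dna_volume_ul = 40, rna_ng = 900,
#'                      rin = 4.9, tumour_cell_pct = 80))
assess_specimen <- function(specimen) {
  s <- as.list(specimen)
  for (nm in c("dsdna_ng", "dna_volume_ul", "rna_ng", "tumour_cell_pct")) {
    if (is.null(s[[nm]]) || is.na(s[[nm]]) || s[[nm]] < 0) {
      stop(sprintf("specimen field '%s' must be a nonnegative number", nm),
           call. = FALSE)
    }
  }
  th <- QC_THRESHOLDS
  reasons <- character()
  meth <- s$dsdna_ng > th$dsdna_ng && s$dna_volume_ul < th$dna_volume_ul
  if (s$dsdna_ng <= th$dsdna_ng) reasons <- c(reasons, "low_dna_yield")
  if (s$dna_volume_ul >= th$dna_volume_ul) reasons <- c(reasons, "dna_volume_too_large")
  rin_missing <- is.null(s$rin) || is.na(s$rin)
  rna <- !rin_missing && s$rna_ng > th$rna_ng && s$rin > th$rin
  if (s$rna_ng <= th$rna_ng) reasons <- c(reasons, "low_rna_yield")
  if (rin_missing) {
    reasons <- c(reasons, "rin_missing")
  } else if (s$rin <= th$rin) {
    reasons <- c(reasons, "low_rin")
  }
  # full panel additionally requires methylation eligibility, so the
  # eligibility hierarchy (full panel => methylation) always holds
  full <- s$dsdna_ng > th$full_panel_ng && meth
  if (s$dsdna_ng <= th$full_panel_ng) reasons <- c(reasons, "below_full_panel_dna")
  tumour <- s$tumour_cell_pct >= th$tumour_cell_pct
  if (!tumour) reasons <- c(reasons, "low_tumour_content")
  structure(list(methylation_eligible = meth, rnaseq_eligible = rna,
                 full_panel_eligible = full, tumour_content_ok = tumour,
                 reasons = reasons),
            class = "qc_decision")
}

#' Assess every specimen of a cohort
#'
#' @param specimens data.frame of specimens (one row each, columns as in
#'   [assess_specimen()], plus optional `patient_id`).
#' @return data.frame with one row per specimen: `patient_id`, the four
#'   eligibility flags, and `reasons` (semicolon-separated codes).
#' @export
assess_specimens <- function(specimens) {
  n <- nrow(specimens)
  ids <- if ("patient_id" %in% names(specimens)) specimens$patient_id
         else sprintf("S%04d", seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    d <- assess_specimen(specimens[i, , drop = FALSE])
    data.frame(patient_id = ids[i],
               methylation_eligible = d$methylation_eligible,
               rnaseq_eligible = d$rnaseq_eligible,
               full_panel_eligible = d$full_panel_eligible,
               tumour_content_ok = d$tumour_content_ok,
               reasons = paste(d$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!n) {
    return(data.frame(patient_id = character(), methylation_eligible = logical(),
                      rnaseq_eligible = logical(), full_panel_eligible = logical(),
                      tumour_content_ok = logical(), reasons = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Summarise QC decisions over a cohort
#'
#' @param decisions data.frame from [assess_specimens()] (nonempty).
#' @return a list of class `qc_summary`: `n`, per-class counts and raw/rounded
#'   percentages, and a reason-code frequency table.
#' @export
summarize_qc <- function(decisions) {
  if (!is.data.frame(decisions) || nrow(decisions) == 0) {
    stop("summarize_qc() requires a nonempty set of QC decisions", call. = FALSE)
  }
  n <- nrow(decisions)
  classes <- c("methylation_eligible", "rnaseq_eligible",
               "full_panel_eligible", "tumour_content_ok")
  counts <- vapply(classes, function(cl) sum(decisions[[cl]]), integer(1))
  pct <- lapply(classes, function(cl) as_percent(sum(decisions[[cl]]), n))
  names(pct) <- classes
  reason_codes <- unlist(strsplit(decisions$reasons[decisions$reasons != ""], ";"))
  reasons <- if (length(reason_codes)) table(reason_codes) else table(character())
  structure(list(n = n, counts = counts, percent = pct, reasons = reasons),
            class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat("<qc_summary> n =", x$n, "\n")
  for (cl in names(x$counts)) {
    cat(sprintf("  %-22s %s\n", cl, fmt_pct(x$counts[[cl]], x$n)))
  }
  if (length(x$reasons)) {
    cat("  reasons:", paste(sprintf("%s=%d", names(x$reasons), x$reasons),
                            collapse = " "), "\n")
  }
  invisible(x)
}
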