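#' Published marginal counts of the emulated national audit cohort
#'
#' The reference national medulloblastoma audit that this package's defaults
#' emulate reported its results as marginal counts (confusion-table margins,
#' funnel counts, review outcomes) rather than per-patient data. This function
#' returns those counts so worked examples and benchmarks can be recomputed
#' from them by the package's operations. Per-patient tables reconstructed
#' from these marginals are synthetic: they reproduce the published margins
#' exactly but are not the original patient-level data.
#'
#' @return a nested list of counts:
#' \describe{
#'   \item{cohort}{`n` (135), `age_eligible` (115).}
#'   \item{mlpa_myc}{MLPA vs iFISH MYC confusion: tp 7, fn 2, fp 11, tn 88.}
#'   \item{mlpa_mycn}{MLPA vs iFISH MYCN: tp 9, fn 3, fp 10, tn 93.}
#'   \item{array_mycn}{array vs iFISH MYCN: tp 9, fn 3, fp 0, tn 103.}
#'   \item{wnt_assays}{n WNT-consensus positive (14) and measured cohort
#'     size for the methylation/RNA-seq comparison (with zero discordances).}
#'   \item{ihc_blinded}{blinded three-pathologist review: 32 cases, 25
#'     concordant with the primary central review.}
#'   \item{variant_review}{135 cases: 105 locally assigned, 10 changed,
#'     30 assigned, 7 centrally unresolved.}
#'   \item{funnel}{age_eligible 115, assay_failures 14, turnaround 13,
#'     bio_high_risk 13, r_plus 11, m_plus 25, eligible 39, wnt_arm 10.}
#'   \item{who}{class counts: WNT 14, SHH TP53-mutant 7, SHH wild-type 26,
#'     Group3 33, Group4 49, unclassifiable 6.}
#'   \item{risk}{115 assessable patients, 33 with altered risk status.}
#' }
#' @export
reference_counts <- function() {
  list(
    cohort = list(n = 135L, age_eligible = 115L),
    mlpa_myc = list(tp = 7L, fn = 2L, fp = 11L, tn = 88L),
    mlpa_mycn = list(tp = 9L, fn = 3L, fp = 10L, tn = 93L),
    array_mycn = list(tp = 9L, fn = 3L, fp = 0L, tn = 103L),
    wnt_assays = list(n_positive = 14L, n_measured = 129L),
    ihc_blinded = list(n = 32L, n_concordant = 25L),
    variant_review = list(n = 135L, local_assigned = 105L, changed = 10L,
                          assigned = 30L, unresolved = 7L),
    funnel = list(age_eligible = 115L, assay_failures = 14L, turnaround = 13L,
                  bio_high_risk = 13L, r_plus = 11L, m_plus = 25L,
                  eligible = 39L, wnt_arm = 10L),
    who = list(WNT_activated = 14L, SHH_TP53mut = 7L, SHH_TP53wt = 26L,
               Group3 = 33L, Group4 = 49L, unclassifiable = 6L),
    risk = list(n = 115L, altered = 33L)
  )
}

#' Synthetic per-case tables reproducing the published marginals
#'
#' Expands [reference_counts()] into per-case data frames on which the
#' package's rule engines and benchmarking operations can run. The expansion
#' is deterministic and exact in every published margin; within-margin case
#' ordering is arbitrary.
#'
#' @return list of data frames / vectors:
#' \describe{
#'   \item{variant_review}{`local_variant`, `central_variant` for 135 cases.}
#'   \item{eligibility}{per-patient integrated records for the 135-patient
#'     funnel (fields of [assess_eligibility()]).}
#'   \item{risk}{per-patient records for the 115 risk-assessable patients
#'     (fields of [compute_risk_delta()]).}
#'   \item{who}{`subgroup`, `tp53_mut` for 135 patients.}
#'   \item{ihc_blinded}{`primary`, `blinded` consensus flags for 32 cases.}
#' }
#' @export
reference_case_tables <- function() {
  rc <- reference_counts()

  vr <- rc$variant_review
  concordant <- vr$local_assigned - vr$changed - vr$unresolved
  variant_review <- data.frame(
    local_variant = c(rep("CLA", concordant), rep("DN", vr$changed),
                      rep("CLA", vr$unresolved),
                      rep("unassigned", vr$n - vr$local_assigned)),
    central_variant = c(rep("CLA", concordant), rep("CLA", vr$changed),
                        rep("MBNOS", vr$unresolved),
                        rep("CLA", vr$assigned)),
    stringsAsFactors = FALSE)

  fu <- rc$funnel
  n_total <- rc$cohort$n
  rec <- function(n, age = 10, complete = TRUE, late = FALSE, myc = FALSE,
                  lca = FALSE, r_plus = FALSE, m_plus = FALSE, wnt = FALSE) {
    if (n == 0) return(NULL)
    data.frame(age_years = age,
               metastatic = m_plus, incomplete_resection = r_plus,
               myc_amp = myc, mycn_amp = FALSE,
               variant = if (lca) "LCA" else "CLA",
               subgroup = if (complete) "Group4" else "NC",
               surgery_to_receipt_days = if (late) 20 else 5,
               receipt_to_report_days = if (late) 40 else 20,
               wnt_positive = wnt,
               stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  eligibility <- do.call(rbind, list(
    rec(n_total - fu$age_eligible, age = 2),              # outside age window
    rec(fu$assay_failures, complete = FALSE),             # assay failures
    rec(fu$turnaround, late = TRUE),                      # late reporting
    rec(fu$bio_high_risk, myc = TRUE),                    # MYC(N)/LCA
    rec(fu$r_plus, r_plus = TRUE),                        # incomplete resection
    rec(fu$m_plus, m_plus = TRUE),                        # metastatic
    rec(fu$wnt_arm, wnt = TRUE),                          # eligible, WNT arm
    rec(fu$eligible - fu$wnt_arm)                         # eligible, standard
  ))
  eligibility <- cbind(patient_id = sprintf("F%03d", seq_len(nrow(eligibility))),
                       eligibility)
  rownames(eligibility) <- NULL

  ri <- rc$risk
  rrec <- function(n, local_variant = "CLA", myc = FALSE, central = "CLA",
                   who = "Group4", wnt = FALSE) {
    if (n == 0) return(NULL)
    data.frame(local_variant = local_variant, metastatic = FALSE,
               incomplete_resection = FALSE, myc_amp = myc, mycn_amp = FALSE,
               central_variant = central, who_class = who, wnt_positive = wnt,
               stringsAsFactors = FALSE)[rep(1, n), , drop = FALSE]
  }
  # 33 altered: CPR finds a risk-defining feature the local workup lacked
  # (amplification, LCA, SHH-TP53mut or favourable WNT status).
  risk <- do.call(rbind, list(
    rrec(10, myc = TRUE),                                   # new amplification
    rrec(9, central = "LCA"),                               # new LCA
    rrec(7, who = "SHH_TP53mut"),                           # SHH TP53 mutant
    rrec(7, wnt = TRUE, who = "WNT_activated"),             # favourable WNT
    rrec(ri$n - ri$altered)                                 # unaltered
  ))
  risk <- cbind(patient_id = sprintf("R%03d", seq_len(nrow(risk))), risk)
  rownames(risk) <- NULL

  wc <- rc$who
  who <- data.frame(
    subgroup = c(rep("WNT", wc$WNT_activated),
                 rep("SHH", wc$SHH_TP53mut + wc$SHH_TP53wt),
                 rep("Group3", wc$Group3), rep("Group4", wc$Group4),
                 rep("NC", wc$unclassifiable)),
    tp53_mut = c(rep(FALSE, wc$WNT_activated), rep(TRUE, wc$SHH_TP53mut),
                 rep(FALSE, wc$SHH_TP53wt + wc$Group3 + wc$Group4 +
                       wc$unclassifiable)),
    stringsAsFactors = FALSE)

  ib <- rc$ihc_blinded
  n_discordant <- ib$n - ib$n_concordant
  primary <- rep(c("positive", "negative"), c(14, ib$n - 14))
  blinded <- primary
  blinded[seq_len(n_discordant)] <-
    ifelse(primary[seq_len(n_discordant)] == "positive", "negative", "positive")
  ihc_blinded <- data.frame(primary = primary, blinded = blinded,
                            stringsAsFactors = FALSE)

  list(variant_review = variant_review, eligibility = eligibility,
       risk = risk, who = who, ihc_blinded = ihc_blinded)
}
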