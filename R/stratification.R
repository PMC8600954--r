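# WHO-2016 classification, SIOP-PNET5-MB-style eligibility rules,
# altered-risk accounting and turnaround-time thresholding.

WHO_CLASSES <- c("WNT_activated", "SHH_TP53mut", "SHH_TP53wt",
                 "Group3", "Group4", "unclassifiable")

#' WHO 2016 integrated class from subgroup and TP53 status
#'
#' WNT maps to WNT-activated; SHH splits by TP53 mutation status; Group3 and
#' Group4 pass through (the non-WNT/non-SHH provisional variants); an NC or
#' absent subgroup call is unclassifiable.
#'
#' @param subgroup subgroup label (`"WNT"`, `"SHH"`, `"Group3"`, `"Group4"`,
#'   `"NC"`) or `NA`.
#' @param tp53_mut logical (may be `NA`; an SHH tumour with unknown TP53
#'   status is reported TP53 wild-type, the non-mutant default class).
#' @return a WHO class string.
#' @export
#' @examples
#' classify_who2016("SHH", TRUE)
classify_who2016 <- function(subgroup, tp53_mut = NA) {
  if (is.na(subgroup) || subgroup == "NC") return("unclassifiable")
  switch(subgroup,
         WNT = "WNT_activated",
         SHH = if (isTRUE(tp53_mut)) "SHH_TP53mut" else "SHH_TP53wt",
         Group3 = "Group3",
         Group4 = "Group4",
         stop("unknown subgroup label: ", subgroup, call. = FALSE))
}

#' Trial eligibility decision for one integrated patient record
#'
#' Encodes the standard-risk trial entry rules: age within \[3, 23) years at
#' diagnosis, complete biomarker data, turnaround within limits
#' (surgery-to-receipt and receipt-to-report), no high-risk biology (MYC or
#' MYCN amplification and/or LCA variant) and no high-risk clinical features
#' (incomplete resection R+ or metastatic disease M+). Eligible WNT-consensus-
#' positive patients enter the favourable-risk arm, other eligible patients
#' the standard arm. Unknown fields produce ineligibility with reasons, never
#' errors.
#'
#' @param record list or one-row data.frame with `age_years`, `metastatic`,
#'   `incomplete_resection`, `myc_amp`, `mycn_amp`, `variant` (central call;
#'   `"MBNOS"` or `NA` counts as incomplete data), `subgroup` (`"NC"`/`NA`
#'   incomplete), `surgery_to_receipt_days`, `receipt_to_report_days`,
#'   `wnt_positive` (logical).
#' @param turnaround_limits list with `receipt` (max surgery-to-receipt days)
#'   and `report` (max further receipt-to-report days).
#' @param age_range numeric `(lower, upper)`; eligibility is
#'   `lower <= age < upper`.
#' @return list of class `eligibility_decision` with flags `age_eligible`,
#'   `data_complete`, `turnaround_ok`, `bio_high_risk`, `clinical_high_risk`,
#'   `eligible`, `arm` (`WNT_favourable`, `standard`, `none`) and `reasons`.
#' @export
assess_eligibility <- function(record,
                               turnaround_limits = list(receipt = 10, report = 28),
                               age_range = c(3, 23)) {
  r <- as.list(record)
  reasons <- character()
  age_eligible <- !is.na(r$age_years) &&
    r$age_years >= age_range[1] && r$age_years < age_range[2]
  if (!age_eligible) reasons <- c(reasons, "age")
  required <- c("myc_amp", "mycn_amp", "variant", "subgroup")
  missing_fields <- required[vapply(required, function(f) {
    v <- r[[f]]
    is.null(v) || is.na(v) || identical(v, "MBNOS") || identical(v, "NC")
  }, logical(1))]
  data_complete <- length(missing_fields) == 0
  if (!data_complete) {
    reasons <- c(reasons, paste0("incomplete_data:",
                                 paste(missing_fields, collapse = ",")))
  }
  turnaround_ok <- !is.na(r$surgery_to_receipt_days) &&
    !is.na(r$receipt_to_report_days) &&
    r$surgery_to_receipt_days <= turnaround_limits$receipt &&
    r$receipt_to_report_days <= turnaround_limits$report
  if (!turnaround_ok) reasons <- c(reasons, "turnaround")
  bio_high_risk <- isTRUE(r$myc_amp) || isTRUE(r$mycn_amp) ||
    identical(r$variant, "LCA")
  if (bio_high_risk) reasons <- c(reasons, "bio_high_risk")
  clinical_high_risk <- isTRUE(r$incomplete_resection) || isTRUE(r$metastatic)
  if (clinical_high_risk) {
    reasons <- c(reasons,
                 if (isTRUE(r$incomplete_resection)) "incomplete_resection",
                 if (isTRUE(r$metastatic)) "metastatic")
  }
  eligible <- age_eligible && data_complete && turnaround_ok &&
    !bio_high_risk && !clinical_high_risk
  arm <- if (!eligible) "none"
         else if (isTRUE(r$wnt_positive)) "WNT_favourable" else "standard"
  structure(list(age_eligible = age_eligible, data_complete = data_complete,
                 turnaround_ok = turnaround_ok, bio_high_risk = bio_high_risk,
                 clinical_high_risk = clinical_high_risk, eligible = eligible,
                 arm = arm, reasons = reasons),
            class = "eligibility_decision")
}

#' Eligibility decisions for a cohort table
#'
#' @param records data.frame with the fields of [assess_eligibility()], one
#'   row per patient, plus `patient_id`.
#' @inheritParams assess_eligibility
#' @return data.frame of per-patient flags, arm and reasons.
#' @export
assess_cohort_eligibility <- function(records,
                                      turnaround_limits = list(receipt = 10, report = 28),
                                      age_range = c(3, 23)) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    d <- assess_eligibility(records[i, , drop = FALSE], turnaround_limits, age_range)
    data.frame(patient_id = records$patient_id[i],
               age_eligible = d$age_eligible, data_complete = d$data_complete,
               turnaround_ok = d$turnaround_ok, bio_high_risk = d$bio_high_risk,
               clinical_high_risk = d$clinical_high_risk, eligible = d$eligible,
               arm = d$arm, reasons = paste(d$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Eligibility funnel accounting over a cohort
#'
#' Funnel order (matching the trial's enrolment flow): total -> age-eligible
#' -> complete data and in-time reporting -> no high-risk biology -> no
#' high-risk clinical features -> eligible, split by arm. Each patient is
#' counted in the first exclusion stage that applies. Percentages use the
#' age-eligible denominator (the trial-relevant population) and carry
#' raw/rounded values.
#'
#' @param decisions data.frame from [assess_cohort_eligibility()] (nonempty).
#' @return list of class `eligibility_funnel`: `counts` (named stage counts),
#'   `arms`, `percent_eligible` (of age-eligible), `exclusions` (stage-wise).
#' @export
cohort_accounting <- function(decisions) {
  if (!is.data.frame(decisions) || nrow(decisions) == 0) {
    stop("cohort_accounting() requires nonempty decisions", call. = FALSE)
  }
  n <- nrow(decisions)
  age_ok <- decisions$age_eligible
  complete <- age_ok & decisions$data_complete & decisions$turnaround_ok
  excl_data <- age_ok & !decisions$data_complete
  excl_turnaround <- age_ok & decisions$data_complete & !decisions$turnaround_ok
  excl_bio <- complete & decisions$bio_high_risk
  excl_clin <- complete & !decisions$bio_high_risk & decisions$clinical_high_risk
  eligible <- decisions$eligible
  counts <- c(total = n, age_eligible = sum(age_ok),
              complete_in_time = sum(complete),
              excluded_incomplete_data = sum(excl_data),
              excluded_turnaround = sum(excl_turnaround),
              excluded_bio_high_risk = sum(excl_bio),
              excluded_clinical_high_risk = sum(excl_clin),
              eligible = sum(eligible))
  arms <- c(WNT_favourable = sum(decisions$arm == "WNT_favourable"),
            standard = sum(decisions$arm == "standard"))
  structure(list(counts = counts, arms = arms,
                 percent_eligible = as_percent(sum(eligible), sum(age_ok)),
                 percent_wnt_arm = as_percent(arms[["WNT_favourable"]],
                                              sum(eligible))),
            class = "eligibility_funnel")
}

#' @export
print.eligibility_funnel <- function(x, ...) {
  cat("<eligibility_funnel>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-28s %d\n", nm, x$counts[[nm]]))
  cat("  arms: WNT_favourable =", x$arms[["WNT_favourable"]],
      ", standard =", x$arms[["standard"]], "\n")
  cat("  eligible of age-eligible:",
      fmt_pct(x$counts[["eligible"]], x$counts[["age_eligible"]]), "\n")
  invisible(x)
}

#' Risk-status change attributable to central review
#'
#' The baseline (pre-review) risk uses only what existed locally: the local
#' histological variant and clinical stage (`high` when local LCA, M+ or R+;
#' `unknown` when the local variant is unassigned and clinical stage carries
#' no high-risk feature). The central (post-review) risk is `high` with
#' MYC/MYCN amplification, central LCA, or SHH-TP53-mutant status;
#' `favourable` when WNT-consensus positive; otherwise `standard`. The risk
#' status is `altered` when the two differ and the central risk is known.
#'
#' @param record list or one-row data.frame with `local_variant`,
#'   `metastatic`, `incomplete_resection`, `myc_amp`, `mycn_amp`,
#'   `central_variant`, `who_class`, `wnt_positive`.
#' @return list of class `risk_delta`: `baseline_risk`, `cpr_risk`, `altered`.
#' @export
compute_risk_delta <- function(record) {
  r <- as.list(record)
  clinical_high <- isTRUE(r$metastatic) || isTRUE(r$incomplete_resection)
  baseline <- if (clinical_high || identical(r$local_variant, "LCA")) "high"
              else if (identical(r$local_variant, "unassigned") ||
                       is.na(r$local_variant %||% NA)) "unknown"
              else "standard"
  cpr_known <- !is.null(r$who_class) && !identical(r$who_class, "unclassifiable")
  cpr <- if (isTRUE(r$myc_amp) || isTRUE(r$mycn_amp) ||
             identical(r$central_variant, "LCA") ||
             identical(r$who_class, "SHH_TP53mut") || clinical_high) "high"
         else if (isTRUE(r$wnt_positive)) "favourable"
         else if (cpr_known && !identical(r$central_variant, "MBNOS")) "standard"
         else "unknown"
  structure(list(baseline_risk = baseline, cpr_risk = cpr,
                 altered = cpr != "unknown" && cpr != baseline),
            class = "risk_delta")
}

#' Risk deltas for a cohort table
#'
#' @param records data.frame with the fields of [compute_risk_delta()] plus
#'   `patient_id`.
#' @return data.frame `patient_id`, `baseline_risk`, `cpr_risk`, `altered`.
#' @export
compute_cohort_risk_deltas <- function(records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    d <- compute_risk_delta(records[i, , drop = FALSE])
    data.frame(patient_id = records$patient_id[i],
               baseline_risk = d$baseline_risk, cpr_risk = d$cpr_risk,
               altered = d$altered, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean-plus-one-SD turnaround thresholds and late flags
#'
#' The late threshold for a processing stage is the sample mean plus one
#' sample standard deviation of its durations; cases strictly above the
#' threshold are flagged late ("exceeded" is strict).
#'
#' @param durations numeric vector of stage durations in days (length >= 2).
#' @param delay_reasons optional character vector (same length) of per-case
#'   delay reason codes joined onto flagged cases.
#' @return list of class `turnaround_summary`: `mean`, `sd`, `threshold`,
#'   `late` (logical vector), `n_late`, `late_reasons` (table, when reasons
#'   given).
#' @export
#' @examples
#' turnaround_thresholds(c(2, 4, 6))
turnaround_thresholds <- function(durations, delay_reasons = NULL) {
  if (length(durations) < 2 || anyNA(durations)) {
    stop("turnaround_thresholds() requires >= 2 non-missing durations",
         call. = FALSE)
  }
  m <- mean(durations)
  s <- stats::sd(durations)
  threshold <- m + s
  late <- durations > threshold
  late_reasons <- NULL
  if (!is.null(delay_reasons)) {
    if (length(delay_reasons) != length(durations)) {
      stop("delay_reasons must match durations in length", call. = FALSE)
    }
    late_reasons <- table(delay_reasons[late])
  }
  structure(list(mean = m, sd = s, threshold = threshold, late = late,
                 n_late = sum(late), late_reasons = late_reasons),
            class = "turnaround_summary")
}

#' @export
print.turnaround_summary <- function(x, ...) {
  cat(sprintf("<turnaround_summary> mean %.2f sd %.2f threshold %.2f; %d late\n",
              x$mean, x$sd, x$threshold, x$n_late))
  invisible(x)
}
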