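# Multi-assay and multi-pathologist consensus: WNT subgroup consensus call,
# IHC pathologist majority, and central-vs-local histological variant
# reconciliation accounting.

IHC_POSITIVITY_PCT <- 10

#' WNT consensus call from a multi-assay panel
#'
#' A tumour is WNT-consensus positive when it carries a CTNNB1 mutation, or
#' when two or more of the four WNT status measures are positive. The four
#' measures and their positivity rules are: nuclear beta-catenin IHC >= 10%;
#' chromosome-6 monosomy; methylation-based subgroup call of WNT; RNA-seq
#' subgroup call of WNT. Unknown fields use three-valued logic: the call is
#' `negative` only when the known fields rule out reaching the rule,
#' `indeterminate` when unknowns could still change the outcome.
#'
#' @param ctnnb1_mut `TRUE`/`FALSE`/`NA`.
#' @param ihc_nuclear_pct nuclear beta-catenin % in \[0, 100\], or `NA`.
#' @param chr6_monosomy `TRUE`/`FALSE`/`NA`.
#' @param meth_subgroup,rna_subgroup subgroup label (`"WNT"`, `"SHH"`,
#'   `"Group3"`, `"Group4"`, `"NC"`) or `NA`.
#' @return list of class `consensus_call`: `status` (`positive`, `negative`,
#'   `indeterminate`), `evidence` (data.frame listing every known measure with
#'   its value and positivity), `rule_fired`.
#' @export
#' @examples
#' call_wnt_consensus(ctnnb1_mut = FALSE, ihc_nuclear_pct = 15,
#'                    chr6_monosomy = TRUE, meth_subgroup = "WNT",
#'                    rna_subgroup = "Group4")
call_wnt_consensus <- function(ctnnb1_mut = NA, ihc_nuclear_pct = NA,
                               chr6_monosomy = NA, meth_subgroup = NA,
                               rna_subgroup = NA) {
  measure_pos <- c(
    ihc = if (is.na(ihc_nuclear_pct)) NA else ihc_nuclear_pct >= IHC_POSITIVITY_PCT,
    chr6_monosomy = as.logical(chr6_monosomy),
    meth_subgroup = if (is.na(meth_subgroup)) NA else identical(meth_subgroup, "WNT"),
    rna_subgroup = if (is.na(rna_subgroup)) NA else identical(rna_subgroup, "WNT")
  )
  values <- c(ihc = ihc_nuclear_pct, chr6_monosomy = chr6_monosomy,
              meth_subgroup = meth_subgroup, rna_subgroup = rna_subgroup)
  known <- !is.na(measure_pos)
  evidence_measures <- c(if (!is.na(ctnnb1_mut)) "ctnnb1_mut", names(measure_pos)[known])
  evidence <- data.frame(
    measure = evidence_measures,
    value = c(if (!is.na(ctnnb1_mut)) as.character(ctnnb1_mut),
              as.character(values[known])),
    positive = c(if (!is.na(ctnnb1_mut)) isTRUE(as.logical(ctnnb1_mut)),
                 unname(measure_pos[known])),
    stringsAsFactors = FALSE)
  if (is.na(ctnnb1_mut) && !any(known)) {
    return(structure(list(status = "indeterminate", evidence = evidence,
                          rule_fired = "insufficient_data"),
                     class = "consensus_call"))
  }
  n_pos <- sum(measure_pos[known])
  n_unknown <- sum(!known)
  if (isTRUE(as.logical(ctnnb1_mut))) {
    status <- "positive"; rule <- "ctnnb1_mutation"
  } else if (n_pos >= 2) {
    status <- "positive"; rule <- "two_or_more_measures"
  } else if (!is.na(ctnnb1_mut) && n_pos + n_unknown < 2) {
    status <- "negative"; rule <- "insufficient_positive_measures"
  } else {
    status <- "indeterminate"; rule <- "unknowns_could_change_outcome"
  }
  structure(list(status = status, evidence = evidence, rule_fired = rule),
            class = "consensus_call")
}

#' @export
print.consensus_call <- function(x, ...) {
  cat("<consensus_call>", x$status, "(", x$rule_fired, ")\n")
  invisible(x)
}

#' Majority consensus across three pathologists
#'
#' Consensus positivity is defined by agreement of at least two of the three
#' reviewing neuropathologists.
#'
#' @param scores logical vector of exactly three per-pathologist positivity
#'   flags.
#' @return single logical: the majority call.
#' @export
pathologist_consensus <- function(scores) {
  if (length(scores) != 3 || anyNA(scores) || !is.logical(scores)) {
    stop("pathologist_consensus() requires exactly 3 non-missing logical scores",
         call. = FALSE)
  }
  sum(scores) >= 2
}

#' Classify one local-vs-central variant review
#'
#' @param local_variant local call: one of CLA/LCA/DN/MBEN or `"unassigned"`.
#' @param central_variant central review call: CLA/LCA/DN/MBEN or `"MBNOS"`.
#' @return outcome string: `concordant` (both definitive and equal), `changed`
#'   (both definitive and different), `assigned` (local unassigned, central
#'   definitive), `unresolved` (central MBNOS).
#' @export
classify_variant_review <- function(local_variant, central_variant) {
  if (!central_variant %in% c(MB_VARIANTS, "MBNOS")) {
    stop("unknown central variant: ", central_variant, call. = FALSE)
  }
  if (!local_variant %in% c(MB_VARIANTS, "unassigned")) {
    stop("unknown local variant: ", local_variant, call. = FALSE)
  }
  if (central_variant == "MBNOS") return("unresolved")
  if (local_variant == "unassigned") return("assigned")
  if (local_variant == central_variant) "concordant" else "changed"
}

#' Reconcile local and central variant calls over a cohort
#'
#' Accounting convention: the `changed` percentage is relative to locally
#' assigned cases; `assigned` and the combined changed-or-assigned percentage
#' are relative to all cases.
#'
#' @param reviews data.frame with `local_variant` and `central_variant`
#'   columns (nonempty); an `outcome` column is recomputed if absent.
#' @return list of class `variant_review_summary`: `n`, `n_local_assigned`,
#'   `counts` (per outcome), and `percent` with raw/rounded values for
#'   `changed` (of locally assigned), `assigned` (of all) and `combined`
#'   (changed or assigned, of all).
#' @export
reconcile_variants <- function(reviews) {
  if (!is.data.frame(reviews) || nrow(reviews) == 0) {
    stop("reconcile_variants() requires a nonempty review set", call. = FALSE)
  }
  outcome <- mapply(classify_variant_review, reviews$local_variant,
                    reviews$central_variant)
  n <- nrow(reviews)
  n_local <- sum(reviews$local_variant != "unassigned")
  counts <- table(factor(outcome, levels = c("concordant", "changed",
                                             "assigned", "unresolved")))
  structure(list(
    n = n, n_local_assigned = n_local, counts = counts,
    percent = list(
      changed = as_percent(counts[["changed"]], n_local),
      assigned = as_percent(counts[["assigned"]], n),
      combined = as_percent(counts[["changed"]] + counts[["assigned"]], n))),
    class = "variant_review_summary")
}

#' @export
print.variant_review_summary <- function(x, ...) {
  cat("<variant_review_summary> n =", x$n,
      "( locally assigned:", x$n_local_assigned, ")\n")
  print(x$counts)
  cat("  changed:", fmt_pct(x$counts[["changed"]], x$n_local_assigned), "\n")
  cat("  assigned:", fmt_pct(x$counts[["assigned"]], x$n), "\n")
  cat("  combined:", fmt_pct(x$counts[["changed"]] + x$counts[["assigned"]], x$n), "\n")
  invisible(x)
}

#' WNT consensus calls for an integrated cohort table
#'
#' @param panel data.frame with columns `patient_id`, `ctnnb1_mut`,
#'   `ihc_nuclear_pct`, `chr6_monosomy`, `meth_subgroup`, `rna_subgroup`
#'   (fields may be `NA`).
#' @return data.frame `patient_id`, `status`, `rule_fired`, `n_positive_measures`.
#' @export
call_cohort_wnt <- function(panel) {
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    cc <- call_wnt_consensus(panel$ctnnb1_mut[i], panel$ihc_nuclear_pct[i],
                             panel$chr6_monosomy[i], panel$meth_subgroup[i],
                             panel$rna_subgroup[i])
    data.frame(patient_id = panel$patient_id[i], status = cc$status,
               rule_fired = cc$rule_fired,
               n_positive_measures = sum(cc$evidence$positive[
                 cc$evidence$measure != "ctnnb1_mut"], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  if (!nrow(panel)) {
    return(data.frame(patient_id = character(), status = character(),
                      rule_fired = character(), n_positive_measures = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
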