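# Confusion matrices, sensitivity/specificity and concordance for any caller
# against a designated truth or consensus standard.

#' Build a confusion summary from paired binary calls
#'
#' Cases whose call failed (`NA`) are excluded from the 2x2 table and counted
#' in `n_failed`; they are never imputed.
#'
#' @param calls logical vector (or `NA` for failed assays), named or paired by
#'   position with `truth`.
#' @param truth logical vector of the reference calls.
#' @param ids optional case identifiers; when given for both vectors via
#'   names, mismatching identifier sets raise an error listing the orphans.
#' @return list of class `confusion_summary`: `tp`, `fp`, `fn`, `tn`,
#'   `n_failed`.
#' @export
#' @examples
#' build_confusion(c(TRUE, FALSE, NA, TRUE), c(TRUE, TRUE, FALSE, FALSE))
build_confusion <- function(calls, truth, ids = NULL) {
  if (!is.null(ids)) {
    names(calls) <- ids
  }
  if (!is.null(names(calls)) && !is.null(names(truth))) {
    orphans <- c(setdiff(names(calls), names(truth)),
                 setdiff(names(truth), names(calls)))
    if (length(orphans)) {
      stop("case ids do not pair up; orphans: ",
           paste(unique(orphans), collapse = ", "), call. = FALSE)
    }
    calls <- calls[names(truth)]
  }
  if (length(calls) != length(truth)) {
    stop("calls and truth must have equal length", call. = FALSE)
  }
  ok <- !is.na(calls) & !is.na(truth)
  c0 <- calls[ok]; t0 <- truth[ok]
  structure(list(tp = sum(c0 & t0), fp = sum(c0 & !t0),
                 fn = sum(!c0 & t0), tn = sum(!c0 & !t0),
                 n_failed = sum(!ok)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> tp=%d fp=%d fn=%d tn=%d (failed=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_failed))
  invisible(x)
}

#' Sensitivity and specificity of a confusion summary
#'
#' Sensitivity = 100 * tp / (tp + fn); specificity = 100 * tn / (tn + fp).
#' An empty margin leaves the statistic undefined (`NA`), flagged rather than
#' reported as zero. Both raw and half-up-rounded percentages are returned.
#'
#' @param confusion a [build_confusion()] result (or a list with `tp`, `fp`,
#'   `fn`, `tn`).
#' @return list with `sensitivity` and `specificity`, each a list
#'   `(raw, rounded)`, plus `undefined` naming any statistic with an empty
#'   margin.
#' @export
#' @examples
#' sensitivity_specificity(list(tp = 9, fn = 3, fp = 0, tn = 100))
sensitivity_specificity <- function(confusion) {
  undefined <- character()
  if (confusion$tp + confusion$fn > 0) {
    sens <- as_percent(confusion$tp, confusion$tp + confusion$fn)
  } else {
    sens <- list(raw = NA_real_, rounded = NA_real_)
    undefined <- c(undefined, "sensitivity")
  }
  if (confusion$fp + confusion$tn > 0) {
    spec <- as_percent(confusion$tn, confusion$tn + confusion$fp)
  } else {
    spec <- list(raw = NA_real_, rounded = NA_real_)
    undefined <- c(undefined, "specificity")
  }
  list(sensitivity = sens, specificity = spec, undefined = undefined)
}

#' Agreement fraction between two paired call vectors
#'
#' @param calls_a,calls_b equal-length vectors of paired calls (any type;
#'   compared elementwise). Pairs with `NA` on either side are dropped.
#' @return list: `n_pairs`, `n_agree`, `percent` (raw/rounded).
#' @export
#' @examples
#' concordance(rep(c("pos", "neg"), c(25, 7)),
#'             rep(c("pos", "neg", "pos"), c(25, 4, 3)))
concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b) || length(calls_a) == 0) {
    stop("concordance() requires nonempty paired vectors of equal length",
         call. = FALSE)
  }
  ok <- !is.na(calls_a) & !is.na(calls_b)
  n <- sum(ok)
  if (n == 0) stop("no complete pairs", call. = FALSE)
  agree <- sum(calls_a[ok] == calls_b[ok])
  list(n_pairs = n, n_agree = agree, percent = as_percent(agree, n))
}

#' Benchmark cohort copy-number platforms against iFISH
#'
#' Treats iFISH as the designated reference ("gold standard"): for each target
#' and each comparison platform (MLPA, methylation-array), builds the
#' confusion summary over patients with a successful call on both platforms
#' and computes sensitivity/specificity.
#'
#' @param cn_calls data.frame from [call_cohort_cn()].
#' @return data.frame: `target`, `platform`, `tp`, `fp`, `fn`, `tn`,
#'   `n_failed`, `sensitivity_raw`, `sensitivity`, `specificity_raw`,
#'   `specificity`.
#' @export
benchmark_cn_platforms <- function(cn_calls) {
  out <- list()
  for (tg in c("MYC", "MYCN")) {
    ref <- cn_calls[cn_calls$platform == "ifish" & cn_calls$target == tg, ]
    ref_ok <- ref[ref$status != "fail", ]
    truth <- stats::setNames(ref_ok$status == "amplified", ref_ok$patient_id)
    for (pl in c("mlpa", "array")) {
      cmp <- cn_calls[cn_calls$platform == pl & cn_calls$target == tg, ]
      call_vec <- stats::setNames(
        ifelse(cmp$status == "fail", NA, cmp$status == "amplified"),
        cmp$patient_id)
      shared <- intersect(names(truth), names(call_vec))
      cs <- build_confusion(call_vec[shared], truth[shared])
      ss <- sensitivity_specificity(cs)
      out[[length(out) + 1]] <- data.frame(
        target = tg, platform = pl, tp = cs$tp, fp = cs$fp, fn = cs$fn,
        tn = cs$tn, n_failed = cs$n_failed,
        sensitivity_raw = ss$sensitivity$raw, sensitivity = ss$sensitivity$rounded,
        specificity_raw = ss$specificity$raw, specificity = ss$specificity$rounded,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
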