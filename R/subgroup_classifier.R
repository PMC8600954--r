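# Molecular subgroup assignment: rank-4 NMF metagenes + linear SVM on
# unit-normalised metagene projections, with bootstrap-resampling confidence.
# Samples classified with < 80% confidence are non-classifiable (NC).

NC_CONFIDENCE_THRESHOLD <- 0.80

#' Fit the metagene model and subgroup classifier
#'
#' Factorises the nonnegative training matrix (features x samples) into four
#' metagenes by NMF (multiplicative updates, best of `n_restarts` random
#' restarts), maps each metagene to the subgroup with the largest mean
#' training projection (greedy bijection), and trains a linear SVM on
#' unit-normalised projections, together with `n_resamples` bootstrap refits
#' of the SVM used downstream as the resampling-confidence ensemble.
#'
#' @param x nonnegative numeric matrix, features x samples (beta values for
#'   methylation, abundances for expression).
#' @param labels subgroup label per sample; all four subgroups must be present
#'   with at least 4 samples each.
#' @param k factorisation rank (4 subgroup metagenes).
#' @param nmf_seed seed for NMF restarts and (offset by one) the bootstrap
#'   ensemble.
#' @param n_restarts NMF random restarts.
#' @param max_iter,tol NMF stopping controls (see [nmf_fit()]).
#' @param n_resamples bootstrap resamples of the training projections; each
#'   refits the SVM, and classification confidence is the fraction of these
#'   refits voting for the modal label.
#' @param svm_cost linear-SVM regularisation cost.
#' @param platform `"methylation"` or `"rnaseq"`; recorded on every call.
#' @return an object of class `metagene_model`: `basis` (features x 4
#'   nonnegative matrix, columns named by subgroup), `training_projections`
#'   (samples x 4), `training_labels`, `svm`, `ensemble`, `nmf_seed`,
#'   `nmf_error`, `platform`.
#' @export
fit_metagenes <- function(x, labels, k = 4L, nmf_seed = 1L, n_restarts = 50L,
                          max_iter = 200L, tol = 1e-6, n_resamples = 1000L,
                          svm_cost = 1, platform = c("methylation", "rnaseq")) {
  platform <- match.arg(platform)
  x <- as.matrix(x)
  if (length(labels) != ncol(x)) {
    stop("length(labels) must equal ncol(x)", call. = FALSE)
  }
  missing <- setdiff(MB_SUBGROUPS, unique(labels))
  if (length(missing)) {
    stop("training set is missing subgroup(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(labels, levels = MB_SUBGROUPS))
  if (any(counts < 4)) {
    stop("need >= 4 training samples per subgroup; short: ",
         paste(names(counts)[counts < 4], collapse = ", "), call. = FALSE)
  }
  fit <- nmf_fit(x, k = k, seed = nmf_seed, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol)
  P <- t(fit$H)  # samples x k
  # Greedy bijection metagene -> subgroup by maximal mean projection per label.
  mean_proj <- vapply(MB_SUBGROUPS, function(sg) {
    colMeans(P[labels == sg, , drop = FALSE])
  }, numeric(k))  # k x 4 (metagene x subgroup)
  assign <- rep(NA_integer_, 4)  # subgroup index -> metagene index
  m <- mean_proj
  for (step in 1:4) {
    ij <- arrayInd(which.max(m), dim(m))
    assign[ij[2]] <- ij[1]
    m[ij[1], ] <- -Inf
    m[, ij[2]] <- -Inf
  }
  W <- fit$W[, assign, drop = FALSE]
  colnames(W) <- MB_SUBGROUPS
  P <- P[, assign, drop = FALSE]
  colnames(P) <- MB_SUBGROUPS
  Pn <- unit_rows(P)
  y <- factor(labels, levels = MB_SUBGROUPS)
  svm_main <- e1071::svm(Pn, y, kernel = "linear", cost = svm_cost, scale = FALSE)
  ensemble <- with_seed(nmf_seed + 1L, {
    lapply(seq_len(n_resamples), function(b) {
      repeat {
        idx <- sample(nrow(Pn), replace = TRUE)
        if (length(unique(labels[idx])) == 4L) break
      }
      e1071::svm(Pn[idx, , drop = FALSE], y[idx], kernel = "linear",
                 cost = svm_cost, scale = FALSE)
    })
  })
  structure(list(basis = W, training_projections = P, training_labels = labels,
                 svm = svm_main, ensemble = ensemble, nmf_seed = nmf_seed,
                 nmf_error = fit$error, platform = platform,
                 classifier_params = list(kernel = "linear", cost = svm_cost,
                                          n_resamples = n_resamples)),
            class = "metagene_model")
}

unit_rows <- function(P) {
  nrm <- sqrt(rowSums(P^2))
  nrm[nrm == 0] <- 1
  P / nrm
}

#' @export
print.metagene_model <- function(x, ...) {
  cat("<metagene_model>", x$platform, "platform;",
      nrow(x$basis), "features x", ncol(x$basis), "metagenes;",
      length(x$ensemble), "bootstrap SVMs; NMF error",
      format(x$nmf_error, digits = 4), "\n")
  invisible(x)
}

#' Classify profiles into molecular subgroups with resampling confidence
#'
#' Each profile is projected onto the metagene basis by nonnegative least
#' squares, unit-normalised, and voted on by the model's bootstrap SVM
#' ensemble. The call label is the modal vote; confidence is the fraction of
#' votes agreeing with it. Calls with confidence below 0.80 are labelled `NC`
#' (non-classifiable).
#'
#' @param x numeric matrix (features x samples) or a single profile vector;
#'   feature dimension must match the model basis.
#' @param model a [fit_metagenes()] model.
#' @param n_resamples optionally use only the first `n_resamples` ensemble
#'   members (defaults to the whole ensemble).
#' @return data.frame with one row per profile: `sample`, `label` (subgroup or
#'   `"NC"`), `confidence`, `modal_label` (modal vote regardless of the NC
#'   rule), `platform`.
#' @export
classify_cohort <- function(x, model, n_resamples = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (nrow(x) != nrow(model$basis)) {
    stop(sprintf("profile dimension (%d) does not match model basis (%d)",
                 nrow(x), nrow(model$basis)), call. = FALSE)
  }
  ens <- model$ensemble
  if (!is.null(n_resamples)) ens <- ens[seq_len(min(n_resamples, length(ens)))]
  P <- unit_rows(t(nnls_project(x, model$basis)))
  colnames(P) <- MB_SUBGROUPS
  votes <- matrix(0L, nrow = nrow(P), ncol = 4,
                  dimnames = list(NULL, MB_SUBGROUPS))
  for (m in ens) {
    pred <- as.character(stats::predict(m, P))
    for (sg in MB_SUBGROUPS) votes[, sg] <- votes[, sg] + (pred == sg)
  }
  modal <- MB_SUBGROUPS[max.col(votes, ties.method = "first")]
  confidence <- votes[cbind(seq_len(nrow(P)), match(modal, MB_SUBGROUPS))] /
    length(ens)
  label <- ifelse(confidence < NC_CONFIDENCE_THRESHOLD, "NC", modal)
  data.frame(sample = colnames(x) %||% sprintf("S%04d", seq_len(nrow(P))),
             label = label, confidence = confidence, modal_label = modal,
             platform = model$platform, stringsAsFactors = FALSE)
}

#' @rdname classify_cohort
#' @param profile a single profile (numeric vector).
#' @return `classify()` returns a list of class `subgroup_call` with `label`,
#'   `confidence`, `platform`.
#' @export
classify <- function(profile, model, n_resamples = NULL) {
  res <- classify_cohort(matrix(profile, ncol = 1), model, n_resamples)
  structure(list(label = res$label, confidence = res$confidence,
                 platform = model$platform),
            class = "subgroup_call")
}

#' @rdname classify_cohort
#' @export
classify_expression <- function(profile, model, n_resamples = NULL) {
  if (model$platform != "rnaseq") {
    stop("classify_expression() requires a model fitted with platform = 'rnaseq'",
         call. = FALSE)
  }
  classify(profile, model, n_resamples)
}

#' @export
print.subgroup_call <- function(x, ...) {
  cat(sprintf("<subgroup_call> %s (confidence %.3f, %s)\n",
              x$label, x$confidence, x$platform))
  invisible(x)
}
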