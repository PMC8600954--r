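# Rank-k non-negative matrix factorisation by multiplicative updates
# (Frobenius objective), best-of-R random restarts. V (features x samples) is
# approximated by W (features x k) %*% H (k x samples). W is drawn at random
# per restart; H is initialised by nonnegative least squares per sample, which
# makes the fit equivariant under sample permutation.

#' Non-negative matrix factorisation (multiplicative updates)
#'
#' @param V nonnegative matrix, features x samples.
#' @param k factorisation rank.
#' @param seed integer seed governing the random restarts.
#' @param n_restarts number of random restarts; the fit with the lowest
#'   reconstruction error is kept.
#' @param max_iter maximum multiplicative-update iterations per restart.
#' @param tol relative change in reconstruction error below which a restart
#'   stops early.
#' @return list with `W`, `H`, `error` (Frobenius reconstruction error),
#'   `restart` (index of the winning restart), `iterations`.
#' @export
nmf_fit <- function(V, k = 4L, seed = 1L, n_restarts = 50L,
                    max_iter = 200L, tol = 1e-6) {
  if (any(V < 0)) stop("NMF input must be nonnegative", call. = FALSE)
  if (ncol(V) < k) stop("need at least k samples", call. = FALSE)
  eps <- .Machine$double.eps
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      W <- matrix(stats::runif(nrow(V) * k, 0.1, 1), nrow = nrow(V))
      H <- nnls_project(V, W)
      err_prev <- Inf
      it <- 0L
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, V)) / (crossprod(W, W) %*% H + eps)
        W <- W * (V %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
        err <- norm(V - W %*% H, "F")
        if (is.finite(err_prev) && abs(err_prev - err) <= tol * max(err_prev, eps)) {
          err_prev <- err
          break
        }
        err_prev <- err
      }
      if (is.null(best) || err_prev < best$error) {
        best <- list(W = W, H = H, error = err_prev, restart = r, iterations = it)
      }
    }
  })
  # Scale so each metagene (column of W) has unit L2 norm; absorb into H.
  nrm <- sqrt(colSums(best$W^2))
  nrm[nrm == 0] <- 1
  best$W <- sweep(best$W, 2, nrm, "/")
  best$H <- sweep(best$H, 1, nrm, "*")
  best
}

#' Project samples onto a fixed nonnegative basis
#'
#' Solves one nonnegative least-squares problem per sample (column of `V`)
#' against the basis `W`.
#'
#' @param V features x samples matrix.
#' @param W features x k nonnegative basis.
#' @return k x samples matrix of nonnegative coefficients.
#' @export
nnls_project <- function(V, W) {
  k <- ncol(W)
  H <- matrix(0, nrow = k, ncol = ncol(V),
              dimnames = list(NULL, colnames(V)))
  for (j in seq_len(ncol(V))) {
    H[, j] <- pracma::lsqnonneg(W, V[, j])$x
  }
  H
}
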