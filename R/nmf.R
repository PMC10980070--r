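#' Non-negative matrix factorization by multiplicative updates
#'
#' Decomposes a non-negative matrix `G` (phyla x conditions growth folds) as
#' `G ~ W %*% H` with `W` (phyla x rank) and `H` (rank x conditions)
#' non-negative, minimizing the Frobenius reconstruction error with the
#' classical multiplicative update rules (which never increase the
#' objective). Several seeded random restarts are run and the best kept.
#'
#' At rank 2 the two rows of `H` are interpretable as two community growth
#' modes (e.g. a mode active under resurgent growth and a mode peaking at
#' moderate perturbations), and the rows of `W` give each phylum's loading
#' on the modes.
#'
#' @param G Non-negative numeric matrix.
#' @param rank Factorization rank (default 2).
#' @param seed RNG seed for the random initializations (default 0).
#' @param n_restarts Random restarts (default 5).
#' @param max_iter Maximum update iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @return Object of class `"nmf_fit"`: `W`, `H`, `variance_explained`
#'   (\eqn{1 - \|G - WH\|_F^2 / \|G\|_F^2}), `objective` (trace of the best
#'   restart), `iterations`, `converged`.
#' @examples
#' G <- outer(runif(8), runif(5)) + outer(runif(8), runif(5))  # exact rank 2
#' f <- nmf(G, rank = 2)
#' f$variance_explained
#' @export
nmf <- function(G, rank = 2, seed = 0, n_restarts = 5,
                max_iter = 2000, tol = 1e-10) {
  G <- as.matrix(G)
  if (any(G < 0)) stop("'G' must be non-negative")
  if (all(G == 0)) stop("'G' is all zero: nothing to factorize")
  n <- nrow(G); m <- ncol(G)
  eps <- .Machine$double.eps
  gnorm2 <- sum(G^2)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(n * rank, 0.1, 1), n, rank) * sqrt(mean(G) / rank)
    H <- matrix(stats::runif(rank * m, 0.1, 1), rank, m) * sqrt(mean(G) / rank)
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, G)) / (crossprod(W) %*% H + eps)
      W <- W * (G %*% t(H)) / (W %*% tcrossprod(H) + eps)
      e <- sum((G - W %*% H)^2)
      obj <- c(obj, e)
      if (is.finite(prev) && prev - e <= tol * max(prev, eps)) break
      prev <- e
    }
    if (is.null(best) || e < best$e)
      best <- list(W = W, H = H, e = e, obj = obj, iter = it,
                   converged = it < max_iter)
  }
  structure(list(W = best$W, H = best$H,
                 variance_explained = 1 - best$e / gnorm2,
                 objective = best$obj, iterations = best$iter,
                 converged = best$converged, rank = rank, seed = seed),
            class = "nmf_fit")
}

#' Rank-2 NMF of a growth-fold matrix
#'
#' Convenience wrapper around [nmf()] at rank 2, the decomposition used for
#' the phylum growth matrix.
#'
#' @inheritParams nmf
#' @return See [nmf()].
#' @export
nmf_rank2 <- function(G, seed = 0, n_restarts = 5, max_iter = 2000,
                      tol = 1e-10)
  nmf(G, rank = 2, seed = seed, n_restarts = n_restarts,
      max_iter = max_iter, tol = tol)

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("NMF fit: rank %d, %d iterations, variance explained %.2f%%\n",
              x$rank, x$iterations, 100 * x$variance_explained))
  invisible(x)
}
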