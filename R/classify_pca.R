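# Principal component reduction for the highly collinear voltage features.
#
# A single PCA transform is fitted on the training frame matrix and shared by
# all per-element classifiers of a PCA-variant bank. Columns are centered
# and scaled; loadings carry a deterministic sign convention (the
# largest-magnitude entry of each loading is positive) so the transform is
# reproducible across platforms.

#' Fit a PCA transform
#'
#' @param X n x m numeric matrix.
#' @param retain Either an integer component count, or a variance fraction
#'   in `(0, 1]`: the smallest count whose cumulative explained-variance
#'   ratio reaches the fraction. Default retains 99.99% of variance.
#' @param scale Scale columns to unit variance before rotation (default TRUE).
#' @return A `pca_transform` with `center`, `scale`, orthonormal `loadings`,
#'   `var_ratio` (all components) and the retained count `k`.
#' @export
fit_pca <- function(X, retain = 0.9999, scale = TRUE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  sv <- svd(Xs)
  ev <- sv$d^2
  var_ratio <- ev / sum(ev)
  if (retain >= 1 && retain == as.integer(retain) && retain != 1) {
    k <- min(as.integer(retain), ncol(X))
  } else if (retain == 1) {
    k <- ncol(X)
  } else if (retain > 0 && retain < 1) {
    k <- which(cumsum(var_ratio) >= retain - 1e-12)[1L]
  } else {
    stop("retain must be a component count or a variance fraction in (0, 1]",
         call. = FALSE)
  }
  W <- sv$v
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(center = ctr, scale = scl,
                 loadings = W[, seq_len(k), drop = FALSE],
                 var_ratio = var_ratio, k = k),
            class = "pca_transform")
}

#' Project data into the retained principal subspace
#' @param pca A `pca_transform`.
#' @param X n x m matrix or length-m vector.
#' @return n x k score matrix.
#' @export
transform_pca <- function(pca, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  Xs <- sweep(sweep(X, 2L, pca$center), 2L, pca$scale, `/`)
  Xs %*% pca$loadings
}

#' Reconstruct data from principal scores
#' @param pca A `pca_transform`.
#' @param S n x k score matrix.
#' @return n x m matrix on the original scale.
#' @export
inverse_pca <- function(pca, S) {
  if (!is.matrix(S)) S <- matrix(S, nrow = 1L)
  Xs <- S %*% t(pca$loadings)
  sweep(sweep(Xs, 2L, pca$scale, `*`), 2L, pca$center, `+`)
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("<pca_transform> %d of %d components, %.4f%% variance retained\n",
              x$k, length(x$var_ratio), 100 * sum(x$var_ratio[seq_len(x$k)])))
  invisible(x)
}
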