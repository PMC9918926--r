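# Gaussian discriminant classifiers: LDA, QDA and regularized variants.
#
# Estimators follow the textbook per-class forms: priors pi_k = n_k / n,
# class means mu_k, pooled covariance with the 1/(n - 2) divisor (LDA) and
# per-class covariances with 1/(n_k - 1) (QDA). Two regularizations are
# available: the QDA-to-LDA interpolation Sigma_k(alpha) =
# alpha Sigma_k + (1 - alpha) Sigma, and covariance shrinkage toward a
# spherical matrix Sigma_gamma = gamma Sigma + (1 - gamma) sigma2 I with
# sigma2 = trace(Sigma)/m (the average eigenvalue), which is the RDA variant
# used for the reference results. Discriminant scores are computed through
# Cholesky factorizations, never explicit inverses.

#' Fit a Gaussian discriminant classifier
#'
#' @param X n x m numeric predictor matrix.
#' @param y Binary 0/1 response.
#' @param mode One of `"lda"`, `"qda"`, `"rda"`.
#' @param alpha For `mode = "qda"`: optional QDA-to-LDA interpolation weight
#'   in `[0, 1]` applied per class (`alpha = 1` is pure QDA, `alpha = 0`
#'   the pooled covariance).
#' @param gamma For `mode = "rda"` (and optionally `"lda"`): shrinkage
#'   weight toward the spherical matrix `sigma2 I`; `gamma = 1` is plain
#'   LDA, `gamma = 0` a spherical covariance of matched scale.
#' @return A `gaussian_da` object with priors, means and the covariance
#'   factorizations needed for scoring.
#' @export
fit_gaussian <- function(X, y, mode = c("lda", "qda", "rda"),
                         alpha = NULL, gamma = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X); m <- ncol(X)
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)))
  n0 <- sum(y == 0L); n1 <- sum(y == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop("each class needs at least 2 samples for covariance estimation",
         call. = FALSE)
  }
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  C0 <- crossprod(sweep(X0, 2L, mu0))
  C1 <- crossprod(sweep(X1, 2L, mu1))
  Sigma_pooled <- (C0 + C1) / (n - 2)      # pooled, 1/(n-2) divisor
  Sigma0 <- C1_safe(C0, n0)                # per class, 1/(n_k - 1)
  Sigma1 <- C1_safe(C1, n1)

  covs <- switch(mode,
    lda = {
      S <- Sigma_pooled
      if (!is.null(gamma)) S <- shrink_spherical(S, gamma)
      list(S)
    },
    rda = {
      if (is.null(gamma)) gamma <- 0.5
      list(shrink_spherical(Sigma_pooled, gamma))
    },
    qda = {
      if (!is.null(alpha)) {
        stopifnot(alpha >= 0, alpha <= 1)
        list(alpha * Sigma0 + (1 - alpha) * Sigma_pooled,
             alpha * Sigma1 + (1 - alpha) * Sigma_pooled)
      } else {
        list(Sigma0, Sigma1)
      }
    })

  chols <- lapply(covs, function(S) {
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) {
      stop("covariance matrix is singular; use rda shrinkage (gamma < 1) or PCA reduction",
           call. = FALSE)
    }
    ch
  })

  structure(list(
    mode = mode,
    priors = c(n0, n1) / n,
    means = list(mu0, mu1),
    pooled = Sigma_pooled,
    class_cov = list(Sigma0, Sigma1),
    covs = covs,           # covariance(s) actually used: 1 (shared) or 2
    chols = chols,
    alpha = alpha, gamma = gamma,
    m = m
  ), class = "gaussian_da")
}

C1_safe <- function(C, nk) C / (nk - 1)

# Sigma_gamma = gamma * Sigma + (1 - gamma) * sigma2 * I, sigma2 = tr(Sigma)/m.
shrink_spherical <- function(Sigma, gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  m <- ncol(Sigma)
  s2 <- sum(diag(Sigma)) / m
  gamma * Sigma + diag((1 - gamma) * s2, m)
}

#' Discriminant score delta_k(x)
#'
#' Linear (shared covariance): `delta_k = log pi_k + x' S^-1 mu_k -
#' mu_k' S^-1 mu_k / 2`. Quadratic (per-class covariance): `delta_k =
#' log pi_k - (x - mu_k)' S_k^-1 (x - mu_k) / 2 - log det(S_k) / 2`.
#'
#' @param params A fitted `gaussian_da`.
#' @param x Numeric vector (length m) or n x m matrix.
#' @param k Class, 0 or 1.
#' @return Numeric score(s).
#' @export
discriminant_score <- function(params, x, k) {
  stopifnot(inherits(params, "gaussian_da"), k %in% c(0L, 1L))
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$m) stop("input length does not match model", call. = FALSE)
  mu <- params$means[[k + 1L]]
  shared <- length(params$chols) == 1L
  ch <- params$chols[[if (shared) 1L else k + 1L]]
  if (shared) {
    Sinv_mu <- backsolve(ch, backsolve(ch, mu, transpose = TRUE))
    drop(log(params$priors[k + 1L]) + x %*% Sinv_mu -
           0.5 * sum(mu * Sinv_mu))
  } else {
    d <- sweep(x, 2L, mu)
    w <- backsolve(ch, t(d), transpose = TRUE)      # ch' w = d'
    maha <- colSums(w^2)
    logdet <- 2 * sum(log(diag(ch)))
    log(params$priors[k + 1L]) - 0.5 * maha - 0.5 * logdet
  }
}

#' Posterior inclusion probability P(Y = 1 | x)
#'
#' Softmax over the two discriminant scores, computed with max-subtraction
#' for stability. Thresholding the posterior at 0.5 reproduces the argmax
#' decision rule.
#'
#' @param params A fitted `gaussian_da`.
#' @param x Numeric vector or n x m matrix.
#' @return Probability (vector) in `[0, 1]`.
#' @export
posterior_proba <- function(params, x) {
  d0 <- discriminant_score(params, x, 0L)
  d1 <- discriminant_score(params, x, 1L)
  mx <- pmax(d0, d1)
  e0 <- exp(d0 - mx); e1 <- exp(d1 - mx)
  e1 / (e0 + e1)
}

#' @export
print.gaussian_da <- function(x, ...) {
  cat(sprintf("<gaussian_da> mode %s, m = %d, priors (%.3f, %.3f)%s%s\n",
              x$mode, x$m, x$priors[1L], x$priors[2L],
              if (!is.null(x$alpha)) sprintf(", alpha = %.3g", x$alpha) else "",
              if (!is.null(x$gamma)) sprintf(", gamma = %.3g", x$gamma) else ""))
  invisible(x)
}
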