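# Penalized logistic regression with elastic-net regularization.
#
# The penalized likelihood is maximized along a decreasing lambda path
# (glmnet's coordinate descent does the convex optimization); the penalty
# weight is then selected by K-fold cross-validated classification accuracy
# at threshold 0.5, ties broken toward the larger (more regularized) lambda.
# Features are standardized internally; reported coefficients are on the
# original scale and the intercept is unpenalized.

#' Fit an elastic-net logistic regression with accuracy-based CV
#'
#' @param X n x m numeric predictor matrix.
#' @param y Binary 0/1 response of length n.
#' @param alpha Elastic-net mixing parameter in `[0, 1]`: 0 = ridge,
#'   1 = LASSO.
#' @param lambda Optional decreasing penalty grid; by default 50 values
#'   log-spaced over 4 decades down from the smallest lambda that zeroes all
#'   LASSO coefficients.
#' @param nlambda,lambda_min_ratio Grid size and lower-end ratio used when
#'   `lambda` is not supplied.
#' @param folds Number of CV folds K (default 10).
#' @param seed Seed for the fold assignment.
#' @return A `logistic_en` model: original-scale `coefficients`, unpenalized
#'   `intercept`, `alpha`, selected `lambda`, and a `cv` tibble
#'   (lambda, mean fold accuracy).
#' @export
fit_logistic_en <- function(X, y, alpha = 0.5, lambda = NULL,
                            nlambda = 50L, lambda_min_ratio = 1e-4,
                            folds = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)),
            alpha >= 0, alpha <= 1)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present; degenerate elements are handled by train_bank",
         call. = FALSE)
  }
  if (n < 2L * folds) stop("need n >= 2 * folds for cross-validation", call. = FALSE)

  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)

  if (is.null(lambda)) {
    # lambda_max: smallest lambda with an all-zero LASSO solution, scaled for
    # the mixing parameter as in the standard path construction.
    lmax <- max(abs(crossprod(Xs, y - mean(y)))) / (n * max(alpha, 1e-3))
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n))

  acc <- matrix(NA_real_, folds, length(lambda))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (min(sum(y[tr] == 0L), sum(y[tr] == 1L)) < 2L) next
    fit_k <- glmnet::glmnet(Xs[tr, , drop = FALSE], y[tr], family = "binomial",
                            alpha = alpha, lambda = lambda,
                            standardize = FALSE, thresh = 1e-10)
    p <- stats::predict(fit_k, Xs[!tr, , drop = FALSE], type = "response",
                        s = lambda, exact = FALSE)
    acc[k, ] <- colMeans((p >= 0.5) == y[!tr])
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  # ties toward the larger lambda (grid is decreasing, so the first maximum)
  best <- which.max(mean_acc)

  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE, thresh = 1e-10)
  # glmnet may truncate the path; interpolate at the selected lambda
  cf <- as.numeric(stats::coef(fit, s = lambda[best], exact = FALSE))
  beta_s <- cf[-1L]
  a0_s <- cf[1L]
  if (!all(is.finite(beta_s))) {
    stop("elastic-net optimization did not converge to finite coefficients",
         call. = FALSE)
  }
  beta <- beta_s / scl
  intercept <- a0_s - sum(beta * ctr)

  structure(list(
    coefficients = beta,
    intercept = unname(intercept),
    alpha = alpha,
    lambda = lambda[best],
    lambda_grid = lambda,
    cv = tibble::tibble(lambda = lambda, accuracy = mean_acc),
    coef_path = fit$beta,
    scale = list(center = ctr, scale = scl)
  ), class = "logistic_en")
}

#' Predicted inclusion probability from a logistic model
#'
#' Evaluates the logistic response `exp(z) / (1 + exp(z))` with
#' `z = intercept + x . beta`, numerically stable for |z| up to several
#' hundred.
#'
#' @param model A `logistic_en` model (or any list with `coefficients` and
#'   `intercept`).
#' @param x Numeric vector of length m or an n x m matrix.
#' @return Probability (vector) in `[0, 1]`.
#' @export
predict_proba_logistic <- function(model, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(model$coefficients)) {
    stop("input length does not match the model's feature count", call. = FALSE)
  }
  z <- model$intercept + drop(x %*% model$coefficients)
  plogis_stable(z)
}

# Stable logistic function.
plogis_stable <- function(z) {
  p <- numeric(length(z))
  pos <- z >= 0
  p[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  p[!pos] <- ez / (1 + ez)
  p
}

#' @export
print.logistic_en <- function(x, ...) {
  cat(sprintf(
    "<logistic_en> alpha = %.2f, lambda = %.4g, %d / %d nonzero coefficients\n",
    x$alpha, x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}
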