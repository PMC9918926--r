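# Independent oracles and shared fixtures, all built in code.

# Small meshes reused across tests (built once per test file).
unit_square_mesh <- function(h = 0.5, electrodes = 2L, min_angle = 10) {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  build_torso_mesh(sq, electrode_count = electrodes,
                   electrode_arc_fraction = 0.5,
                   target_edge_length = h, min_angle = min_angle)
}

coarse_torso_mesh <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_torso_mesh(target_edge_length = 0.02)
    cache
  }
})

# Unpenalized logistic regression by iteratively reweighted least squares.
irls_logistic <- function(X, y, tol = 1e-12, maxit = 200L) {
  X1 <- cbind(1, X)
  beta <- numeric(ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- p * (1 - p)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(X1, w * X1), crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  list(intercept = beta[1L], coefficients = beta[-1L])
}

# Brute-force best split: exhaustive over every (feature, midpoint threshold)
# pair, minimizing size-weighted child Gini; respects the min_leaf bound.
brute_force_split <- function(X, y, min_leaf = 1L) {
  n <- length(y)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2L) next
    for (t in (xs[-length(xs)] + xs[-1L]) / 2) {
      left <- X[, f] <= t
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      gl <- gini_impurity(c(sum(y[left] == 0L), sum(y[left] == 1L)))
      gr <- gini_impurity(c(sum(y[!left] == 0L), sum(y[!left] == 1L)))
      wg <- (nl * gl + nr * gr) / n
      if (is.null(best) || wg < best$wgini - 1e-15) {
        best <- list(feature = f, threshold = t, wgini = wg)
      }
    }
  }
  best
}

# AUC by concordant-pair counting (ties count half).
pair_count_auc <- function(p, y) {
  pos <- p[y == 1L]
  neg <- p[y == 0L]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force Bayes posterior with explicit Gaussian densities.
bayes_posterior <- function(x, priors, means, covs) {
  dens <- function(mu, S) {
    m <- length(mu)
    d <- x - mu
    exp(-0.5 * drop(t(d) %*% solve(S, d))) / sqrt((2 * pi)^m * det(S))
  }
  f0 <- dens(means[[1L]], covs[[1L]])
  f1 <- dens(means[[2L]], covs[[2L]])
  f1 * priors[2L] / (f0 * priors[1L] + f1 * priors[2L])
}

# Hand-built gaussian_da with supplied parameters (bypasses estimation).
manual_gaussian <- function(priors, means, covs, mode = "qda") {
  structure(list(mode = mode, priors = priors,
                 means = means, covs = covs,
                 chols = lapply(covs, chol),
                 m = length(means[[1L]])),
            class = "gaussian_da")
}

# Closed-form boundary potential for two point-like electrodes on a
# homogeneous disk, evaluated at arbitrary points.
disk_two_point_potential <- function(pts, src, snk, current, sigma) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 2L)
  dB <- sqrt(rowSums(sweep(pts, 2L, snk)^2))
  dA <- sqrt(rowSums(sweep(pts, 2L, src)^2))
  current / (pi * sigma) * (log(dB) - log(dA))
}

expect_half_up <- function(x, printed, digits = 3L) {
  expect_equal(round_half_up(x, digits), printed, tolerance = 1e-12)
}
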