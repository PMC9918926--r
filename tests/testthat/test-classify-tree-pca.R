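test_that("gini impurity matches its closed form", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "all-zero")
})

test_that("perfectly separable 1-D data yields a depth-1 perfect tree", {
  x <- matrix(seq(-1, 1, length.out = 40L), ncol = 1L)
  y <- as.integer(x[, 1L] > 0)
  tr <- fit_tree(x, y, min_leaf = 1L, min_split = 2L)
  expect_equal(nrow(tr$nodes), 3L)          # root + 2 leaves
  expect_equal(mean((predict_tree(tr, x) >= 0.5) == y), 1)
})

test_that("XOR needs depth 2; depth 1 does no better than the split enumeration bound", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c(0L, 1L, 1L, 0L)
  t2 <- fit_tree(X, y, max_depth = 2L, min_leaf = 1L, min_split = 2L,
                 prune = FALSE)
  expect_equal(mean((predict_tree(t2, X) >= 0.5) == y), 1)
  # enumerate all depth-1 trees: best achievable training accuracy
  best_acc <- 0
  for (f in 1:2) for (t in 0.5) {
    pred_l <- mean(y[X[, f] <= t]) >= 0.5
    pred_r <- mean(y[X[, f] > t]) >= 0.5
    acc <- mean(ifelse(X[, f] <= t, pred_l, pred_r) == y)
    best_acc <- max(best_acc, acc)
  }
  t1 <- fit_tree(X, y, max_depth = 1L, min_leaf = 1L, min_split = 2L,
                 prune = FALSE)
  acc1 <- mean((predict_tree(t1, X) >= 0.5) == y)
  expect_equal(acc1, best_acc)
})

test_that("the root split agrees with exhaustive enumeration", {
  # fixed 20-sample instance
  set.seed(6)
  X <- matrix(stats::rnorm(40), 20L, 2L)
  y <- as.integer(X[, 1L] + 0.5 * X[, 2L] + stats::rnorm(20L, 0, 0.5) > 0)
  tr <- fit_tree(X, y, min_leaf = 1L, min_split = 2L, prune = FALSE)
  oracle <- brute_force_split(X, y, min_leaf = 1L)
  got <- eitclass:::best_split(X, y, min_leaf = 1L)
  expect_equal(got$wgini, oracle$wgini, tolerance = 1e-12)
  expect_equal(tr$nodes$feature[1L], oracle$feature)
  # random instances with n <= 30, m <= 3
  for (trial in 1:40) {
    n <- sample(6:30, 1L); m <- sample(1:3, 1L)
    X <- matrix(stats::rnorm(n * m), n, m)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2L) next
    got <- eitclass:::best_split(X, y, min_leaf = 1L)
    oracle <- brute_force_split(X, y, min_leaf = 1L)
    if (is.null(oracle)) {
      expect_null(got)
    } else {
      expect_equal(got$wgini, oracle$wgini, tolerance = 1e-12)
    }
  }
})

test_that("stopping rules produce leaves, not errors, on degenerate input", {
  X <- matrix(1, 30L, 2L)                  # constant predictors
  y <- rep(c(0L, 1L), 15L)
  tr <- fit_tree(X, y)
  expect_equal(nrow(tr$nodes), 1L)
  expect_equal(predict_tree(tr, X)[1L], 0.5)
})

test_that("zero-gain pruning never changes training decisions", {
  set.seed(12)
  X <- matrix(stats::rnorm(400), 100L, 4L)
  y <- as.integer(X[, 1L] - X[, 2L] > 0.3)
  t_full <- fit_tree(X, y, prune = FALSE)
  t_pruned <- fit_tree(X, y, prune = TRUE)
  d_full <- predict_tree(t_full, X) >= 0.5
  d_pruned <- predict_tree(t_pruned, X) >= 0.5
  expect_identical(d_full, d_pruned)
  expect_lte(nrow(t_pruned$nodes), nrow(t_full$nodes))
})

test_that("PCA round-trips, captures exact rank, and has deterministic signs", {
  set.seed(3)
  X <- matrix(stats::rnorm(200), 50L, 4L)
  pc <- fit_pca(X, retain = 1)
  expect_equal(inverse_pca(pc, transform_pca(pc, X)), X, tolerance = 1e-8)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(ncol(X)))), 1e-10)
  expect_true(all(diff(pc$var_ratio) <= 1e-12))
  # rank-2 data: 2 components explain everything
  X2 <- matrix(stats::rnorm(100), 50L, 2L) %*% matrix(stats::rnorm(8), 2L, 4L)
  pc2 <- fit_pca(X2, retain = 0.999)
  expect_equal(pc2$k, 2L)
  expect_equal(sum(pc2$var_ratio[1:2]), 1, tolerance = 1e-10)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(pc$k)) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
  expect_error(fit_pca(X, retain = -0.1), "retain")
})
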