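# Classification tree (CART) grown by greedy Gini-minimizing binary splits.
#
# The splitter is exact and deterministic: every candidate threshold is the
# midpoint between consecutive distinct sorted values of a feature; the
# split minimizing the size-weighted child Gini impurity is chosen, ties
# broken by the lowest feature index and then the lowest threshold. Growth
# stops at the depth bound or the minimum node/leaf sizes; splits with zero
# immediate impurity decrease are admissible (an XOR-like interaction needs
# them), and the pruning pass removes any that never pay off. Leaves predict
# the class-1 fraction of their samples.

#' Gini impurity of a node
#'
#' `1 - sum_d p_d^2` over class proportions; for two classes the value lies
#' in `[0, 0.5]`.
#'
#' @param counts Nonnegative class counts (any number of classes).
#' @return Impurity value.
#' @export
gini_impurity <- function(counts) {
  stopifnot(all(counts >= 0))
  tot <- sum(counts)
  if (tot == 0) stop("gini_impurity: all-zero counts", call. = FALSE)
  1 - sum((counts / tot)^2)
}

# Best split for one node. Returns NULL when no admissible split achieves
# an impurity decrease of at least min_decrease.
best_split <- function(X, y, min_leaf, min_decrease = 0) {
  n <- length(y)
  parent_gini <- gini_impurity(c(n - sum(y), sum(y)))
  best <- NULL
  for (f in seq_len(ncol(X))) {
    x <- X[, f]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cum1 <- cumsum(ys)
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(ok)) next
    i <- i[ok]
    nl <- i; nr <- n - i
    l1 <- cum1[i]; l0 <- nl - l1
    r1 <- cum1[n] - l1; r0 <- nr - r1
    gl <- 1 - (l0 / nl)^2 - (l1 / nl)^2
    gr <- 1 - (r0 / nr)^2 - (r1 / nr)^2
    wg <- (nl * gl + nr * gr) / n
    j <- which.min(wg)  # lowest threshold among equals within this feature
    if (parent_gini - wg[j] >= min_decrease &&
        (is.null(best) || wg[j] < best$wgini - 1e-15)) {
      best <- list(feature = f, threshold = (xs[i[j]] + xs[i[j] + 1L]) / 2,
                   wgini = wg[j])
    }
  }
  best
}

#' Fit a classification tree
#'
#' @param X n x m numeric predictor matrix.
#' @param y Binary 0/1 response.
#' @param max_depth Maximum depth (root = depth 0); default 12.
#' @param min_leaf Minimum samples per leaf; default 5.
#' @param min_split Minimum node size eligible for splitting (default 20,
#'   the canonical CART stopping rule).
#' @param min_decrease Minimum impurity decrease required to split.
#' @param prune Apply zero-gain cost-complexity pruning after growth
#'   (default TRUE): any subtree whose training misclassification count (at
#'   the 0.5 rule) is no better than its root collapsed to a leaf is
#'   removed. This is cost-complexity pruning at alpha = 0, the weakest
#'   form of the standard CART pruning step; it leaves every
#'   impurity-reducing split that actually changes a training decision in
#'   place.
#' @return A `cart_tree`: a node table (tibble) with `feature`, `threshold`,
#'   `left`, `right` for internal nodes and per-node sample counts and
#'   class-1 fraction. Constant predictors yield a single-leaf tree.
#' @export
fit_tree <- function(X, y, max_depth = 12L, min_leaf = 5L, min_split = 20L,
                     min_decrease = 0, prune = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (length(y) < 2L * min_leaf) {
    stop("need n >= 2 * min_leaf samples", call. = FALSE)
  }
  nodes <- list()
  # stack of (sample index set, depth, parent slot, side)
  grow <- function(idx, depth) {
    yy <- y[idx]
    node <- list(feature = NA_integer_, threshold = NA_real_,
                 left = NA_integer_, right = NA_integer_,
                 n = length(idx), n1 = sum(yy), prob = mean(yy))
    id <- length(nodes) + 1L
    nodes[[id]] <<- node
    split <- NULL
    if (depth < max_depth && length(idx) >= max(min_split, 2L * min_leaf) &&
        node$n1 > 0L && node$n1 < node$n) {
      split <- best_split(X[idx, , drop = FALSE], yy, min_leaf, min_decrease)
    }
    if (!is.null(split)) {
      go_left <- X[idx, split$feature] <= split$threshold
      lid <- grow(idx[go_left], depth + 1L)
      rid <- grow(idx[!go_left], depth + 1L)
      nodes[[id]]$feature <<- split$feature
      nodes[[id]]$threshold <<- split$threshold
      nodes[[id]]$left <<- lid
      nodes[[id]]$right <<- rid
    }
    id
  }
  grow(seq_along(y), 0L)
  tbl <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
  if (prune) tbl <- .prune_zero_gain(tbl)
  structure(list(nodes = tbl, m = ncol(X),
                 hyper = list(max_depth = max_depth, min_leaf = min_leaf,
                              min_split = min_split,
                              min_decrease = min_decrease, prune = prune)),
            class = "cart_tree")
}

# Cost-complexity pruning at alpha = 0: collapse any subtree whose total
# leaf misclassification count (0.5 rule) does not beat its root as a leaf.
.prune_zero_gain <- function(tbl) {
  risk_leaf <- pmin(tbl$n1, tbl$n - tbl$n1)
  subtree_risk <- rep(NA_real_, nrow(tbl))
  collapse <- logical(nrow(tbl))
  eval_node <- function(id) {
    if (is.na(tbl$feature[id])) {
      subtree_risk[id] <<- risk_leaf[id]
      return(risk_leaf[id])
    }
    r <- eval_node(tbl$left[id]) + eval_node(tbl$right[id])
    if (r >= risk_leaf[id]) {
      collapse[id] <<- TRUE
      subtree_risk[id] <<- risk_leaf[id]
      risk_leaf[id]
    } else {
      subtree_risk[id] <<- r
      r
    }
  }
  eval_node(1L)
  # mark collapsed internals as leaves; descendants become unreachable
  tbl$feature[collapse] <- NA_integer_
  tbl$threshold[collapse] <- NA_real_
  tbl$left[collapse] <- NA_integer_
  tbl$right[collapse] <- NA_integer_
  # drop unreachable rows and reindex
  keep <- logical(nrow(tbl))
  stack <- 1L
  while (length(stack)) {
    id <- stack[1L]; stack <- stack[-1L]
    keep[id] <- TRUE
    if (!is.na(tbl$feature[id])) stack <- c(stack, tbl$left[id], tbl$right[id])
  }
  remap <- cumsum(keep)
  out <- tbl[keep, ]
  out$left <- ifelse(is.na(out$left), NA_integer_, remap[out$left])
  out$right <- ifelse(is.na(out$right), NA_integer_, remap[out$right])
  out
}

#' Predicted class-1 fraction from a classification tree
#' @param tree A `cart_tree`.
#' @param x Length-m vector or n x m matrix.
#' @return Leaf class-1 fraction(s) in `[0, 1]`.
#' @export
predict_tree <- function(tree, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != tree$m) stop("input length does not match the tree", call. = FALSE)
  nd <- tree$nodes
  cur <- rep.int(1L, nrow(x))
  active <- !is.na(nd$feature[cur])
  while (any(active)) {
    i <- which(active)
    node <- cur[i]
    go_left <- x[cbind(i, nd$feature[node])] <= nd$threshold[node]
    cur[i] <- ifelse(go_left, nd$left[node], nd$right[node])
    active[i] <- !is.na(nd$feature[cur[i]])
  }
  nd$prob[cur]
}

#' @export
print.cart_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$feature))
  cat(sprintf("<cart_tree> %d nodes (%d leaves), m = %d\n",
              nrow(x$nodes), n_leaf, x$m))
  invisible(x)
}
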