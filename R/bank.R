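# One classifier per mesh element.
#
# train_bank() fits the chosen method variant to (X, Y[, e]) for every mesh
# element e. Elements with too few positive labels for the method receive a
# constant-model sentinel that predicts the observed base rate. PCA variants
# fit one shared transform on X and train the per-element models in the
# reduced space. The supported method tags mirror the study's seven
# variants: lr-elastic, lr-ridge, lr-lasso, lda, qda, rda, lda-pca,
# qda-pca, cart.

BANK_METHODS <- c("lr-elastic", "lr-ridge", "lr-lasso",
                  "lda", "qda", "rda", "lda-pca", "qda-pca", "cart")

#' Train a per-element classifier bank
#'
#' @param dataset An `eit_dataset`.
#' @param method One of `"lr-elastic"`, `"lr-ridge"`, `"lr-lasso"`,
#'   `"lda"`, `"qda"`, `"rda"`, `"lda-pca"`, `"qda-pca"`, `"cart"`.
#' @param folds CV folds for penalized logistic regression and for the RDA
#'   shrinkage grid (default 10).
#' @param seed Master seed; per-element sub-seeds are derived from it.
#' @param pca_retain Variance fraction (or component count) retained by the
#'   shared PCA transform of the `*-pca` variants.
#' @param min_pos Minimum positive count below which an element receives the
#'   constant-model sentinel. Default: 1 for CART, 2 for penalized logistic
#'   regression (the smallest class size the optimizer accepts), and `d + 2`
#'   for covariance-based methods (`d` = feature dimension used), so the
#'   class-1 covariance stays positive definite.
#' @param gamma_grid Shrinkage grid searched by CV accuracy for `"rda"`.
#' @param lr_alpha Elastic-net mixing for `"lr-elastic"` (default 0.5).
#' @param tree_args List of [fit_tree()] hyperparameters for `"cart"`.
#' @return An `element_bank`: per-element model list (with constant-model
#'   sentinels), optional shared `pca`, and training metadata.
#' @export
train_bank <- function(dataset, method = "qda-pca", folds = 10L, seed = 1L,
                       pca_retain = 0.9999, min_pos = NULL,
                       gamma_grid = c(0.05, 0.25, 0.5, 0.75, 0.95),
                       lr_alpha = 0.5, tree_args = list()) {
  stopifnot(inherits(dataset, "eit_dataset"))
  if (!method %in% BANK_METHODS) {
    stop("unknown method tag: ", method, call. = FALSE)
  }
  X <- dataset$X
  Y <- dataset$Y
  E <- ncol(Y)
  pca <- NULL
  Xf <- X
  if (method %in% c("lda-pca", "qda-pca")) {
    pca <- fit_pca(X, retain = pca_retain)
    Xf <- transform_pca(pca, X)
  }
  d <- ncol(Xf)
  covariance_based <- method %in% c("lda", "qda", "rda", "lda-pca", "qda-pca")
  if (is.null(min_pos)) {
    min_pos <- if (covariance_based) d + 2L else
      if (startsWith(method, "lr-")) 2L else 1L
  }

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, E)

  gauss_mode <- c("lda" = "lda", "lda-pca" = "lda",
                  "qda" = "qda", "qda-pca" = "qda",
                  "rda" = "rda")[method]

  models <- vector("list", E)
  for (e in seq_len(E)) {
    y <- Y[, e]
    npos <- sum(y)
    if (npos < min_pos || npos > length(y) - min_pos) {
      models[[e]] <- constant_model(mean(y))
      next
    }
    models[[e]] <- switch(method,
      "lr-elastic" = , "lr-ridge" = , "lr-lasso" = {
        a <- switch(method, "lr-elastic" = lr_alpha, "lr-ridge" = 0,
                    "lr-lasso" = 1)
        fit_logistic_en(Xf, y, alpha = a, folds = folds, seed = sub_seeds[e])
      },
      "lda" = , "lda-pca" = , "qda" = , "qda-pca" =
        fit_gaussian(Xf, y, mode = gauss_mode),
      "rda" = fit_rda_cv(Xf, y, gamma_grid, folds, sub_seeds[e]),
      "cart" = do.call(fit_tree, c(list(X = Xf, y = y), tree_args))
    )
  }
  structure(list(
    method = method,
    models = models,
    pca = pca,
    n_elements = E,
    protocol_id = dataset$meta$protocol_id,
    meta = list(folds = folds, seed = seed, min_pos = min_pos,
                pca_retain = if (is.null(pca)) NULL else pca_retain,
                n_train = nrow(X))
  ), class = "element_bank")
}

constant_model <- function(rate) {
  structure(list(rate = rate), class = "constant_model")
}

# RDA: LDA with spherical shrinkage, gamma selected by K-fold CV accuracy
# (smallest classification error), ties toward stronger shrinkage.
fit_rda_cv <- function(X, y, gamma_grid, folds, seed) {
  n <- nrow(X)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(min(folds, n)), n))
  gamma_grid <- sort(gamma_grid)  # ascending: first maximum = most shrinkage
  acc <- vapply(gamma_grid, function(g) {
    hits <- 0L; tot <- 0L
    for (k in unique(fold_id)) {
      tr <- fold_id != k
      y_tr <- y[tr]
      if (sum(y_tr) < 2L || sum(1 - y_tr) < 2L) next
      fit <- tryCatch(fit_gaussian(X[tr, , drop = FALSE], y_tr,
                                   mode = "rda", gamma = g),
                      error = function(e) NULL)
      if (is.null(fit)) next
      p <- posterior_proba(fit, X[!tr, , drop = FALSE])
      hits <- hits + sum((p >= 0.5) == y[!tr])
      tot <- tot + sum(!tr)
    }
    if (tot == 0L) NA_real_ else hits / tot
  }, numeric(1L))
  g_best <- gamma_grid[which.max(acc)]
  fit_gaussian(X, y, mode = "rda", gamma = g_best)
}

# Probability from any per-element model on preprocessed features.
.model_proba <- function(model, Xf) {
  if (inherits(model, "constant_model")) {
    rep.int(model$rate, nrow(Xf))
  } else if (inherits(model, "logistic_en")) {
    predict_proba_logistic(model, Xf)
  } else if (inherits(model, "gaussian_da")) {
    posterior_proba(model, Xf)
  } else if (inherits(model, "cart_tree")) {
    predict_tree(model, Xf)
  } else {
    stop("unknown model type in bank", call. = FALSE)
  }
}

#' Reconstruct an inclusion probability map from a frame
#'
#' Applies every element's classifier to the (identically preprocessed)
#' measurement frame and returns the per-element inclusion probability map.
#'
#' @param bank An `element_bank`.
#' @param frame An `eit_frame` recorded under the bank's training protocol,
#'   or a bare numeric vector of length m.
#' @return A `prob_map`: per-element probabilities in `[0, 1]`.
#' @export
reconstruct <- function(bank, frame) {
  stopifnot(inherits(bank, "element_bank"))
  if (inherits(frame, "eit_frame")) {
    if (!identical(frame$protocol_id, bank$protocol_id)) {
      stop("frame protocol does not match the bank's training protocol",
           call. = FALSE)
    }
    x <- frame$values
  } else {
    x <- as.numeric(frame)
  }
  Xf <- matrix(x, nrow = 1L)
  if (!is.null(bank$pca)) Xf <- transform_pca(bank$pca, Xf)
  p <- vapply(bank$models, function(mod) .model_proba(mod, Xf), numeric(1L))
  new_prob_map(p, bank)
}

# Batch reconstruction: one probability map per row of a frame matrix.
# Returns an n x E matrix; considerably faster than per-frame reconstruct()
# for evaluation over held-out sets.
#' @rdname reconstruct
#' @param frames n x m matrix of frames (one per row).
#' @return `reconstruct_frames()`: an n x E probability matrix.
#' @export
reconstruct_frames <- function(bank, frames) {
  stopifnot(inherits(bank, "element_bank"), is.matrix(frames))
  Xf <- frames
  if (!is.null(bank$pca)) Xf <- transform_pca(bank$pca, Xf)
  P <- matrix(0, nrow(frames), bank$n_elements)
  for (e in seq_len(bank$n_elements)) {
    P[, e] <- .model_proba(bank$models[[e]], Xf)
  }
  P
}

new_prob_map <- function(p, bank = NULL) {
  stopifnot(all(p >= 0), all(p <= 1))
  structure(list(p = as.numeric(p),
                 method = if (is.null(bank)) NA_character_ else bank$method),
            class = "prob_map")
}

#' @export
print.element_bank <- function(x, ...) {
  n_const <- sum(vapply(x$models, inherits, logical(1L), "constant_model"))
  cat(sprintf("<element_bank> method %s, %d elements (%d constant sentinels)%s\n",
              x$method, x$n_elements, n_const,
              if (is.null(x$pca)) "" else
                sprintf(", PCA %d comps", x$pca$k)))
  invisible(x)
}

#' @export
print.prob_map <- function(x, ...) {
  cat(sprintf("<prob_map> %d elements, method %s, mean p = %.3f\n",
              length(x$p), x$method, mean(x$p)))
  invisible(x)
}
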