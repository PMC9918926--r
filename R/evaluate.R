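# Reconstruction scoring: confusion-matrix statistics, agreement measures,
# ROC/AUC, and raster image-quality metrics.
#
# Conventions follow the standard confusion-matrix terminology with the
# presence of an inclusion as the positive case. Rates with an undefined
# denominator are reported as NA (documented sentinel). Rendered reports
# round half-up to 3 decimals, matching the usual table style; raw doubles
# are always kept.

#' Threshold a probability map
#'
#' @param pmap A `prob_map` or bare numeric probability vector.
#' @param t Threshold in `[0, 1]`; the conventional default is 0.5.
#' @return Integer 0/1 vector: 1 iff `p >= t` (boundary inclusive).
#' @export
threshold_map <- function(pmap, t = 0.5) {
  p <- if (inherits(pmap, "prob_map")) pmap$p else as.numeric(pmap)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t > 1) {
    stop("threshold t must lie in [0, 1]", call. = FALSE)
  }
  as.integer(p >= t)
}

#' Confusion counts
#'
#' @param pred Predicted 0/1 labels.
#' @param truth True 0/1 labels of equal length.
#' @return A `confusion_counts` list with `TP`, `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  stopifnot(all(pred %in% c(0L, 1L)), all(truth %in% c(0L, 1L)))
  confusion_counts(TP = sum(pred == 1L & truth == 1L),
                   FP = sum(pred == 1L & truth == 0L),
                   FN = sum(pred == 0L & truth == 1L),
                   TN = sum(pred == 0L & truth == 0L))
}

#' @rdname confusion
#' @param TP,FP,FN,TN Nonnegative counts.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  stopifnot(all(counts >= 0))
  structure(as.list(counts), class = "confusion_counts")
}

.safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Basic fit measures from confusion counts
#'
#' Accuracy, sensitivity (TPR), specificity, positive/negative predictive
#' value, precision (= PPV), F1, prevalence, detection rate, detection
#' prevalence and balanced accuracy. Undefined ratios (zero denominator)
#' are NA.
#'
#' @param counts A `confusion_counts`.
#' @return One-row tibble of rates.
#' @export
fit_measures <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  total <- TP + FP + FN + TN
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sens <- .safe_div(TP, TP + FN)
  spec <- .safe_div(TN, TN + FP)
  ppv <- .safe_div(TP, TP + FP)
  tibble::tibble(
    accuracy = (TP + TN) / total,
    sensitivity = sens,
    specificity = spec,
    pos_pred_value = ppv,
    neg_pred_value = .safe_div(TN, TN + FN),
    precision = ppv,
    f1 = .safe_div(2 * TP, 2 * TP + FP + FN),
    prevalence = (TP + FN) / total,
    detection_rate = TP / total,
    detection_prevalence = (TP + FP) / total,
    balanced_accuracy = (sens + spec) / 2
  )
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement,
#' `kappa = 2 (TP TN - FN FP) / [(TP+FP)(FP+TN) + (TP+FN)(FN+TN)]`,
#' algebraically equal to the usual `(p_o - p_e) / (1 - p_e)` form.
#'
#' @param counts A `confusion_counts`.
#' @return Kappa, or NA when the denominator vanishes.
#' @export
cohens_kappa <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  den <- (TP + FP) * (FP + TN) + (TP + FN) * (FN + TN)
  if (den == 0) return(NA_real_)
  2 * (TP * TN - FN * FP) / den
}

#' McNemar's chi-squared statistic on the discordant counts
#'
#' Raw form `(FP - FN)^2 / (FP + FN)`; continuity-corrected form
#' `(|FP - FN| - 1)^2 / (FP + FN)`. With no discordant elements the
#' statistic is reported as 0 (documented sentinel).
#'
#' @param counts A `confusion_counts`.
#' @param corrected Apply the continuity correction (default FALSE).
#' @return The chi-squared value.
#' @export
mcnemar <- function(counts, corrected = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  FP <- counts$FP; FN <- counts$FN
  if (FP + FN == 0) return(0)
  if (corrected) (abs(FP - FN) - 1)^2 / (FP + FN) else (FP - FN)^2 / (FP + FN)
}

#' ROC curve and AUC
#'
#' Thresholds at every distinct probability (plus sentinels above the
#' maximum); AUC by the trapezoid rule, which equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param pmap A `prob_map` or numeric probability vector.
#' @param truth True 0/1 labels.
#' @return An `roc_curve` object: tibble `curve` (threshold, fpr, tpr) and
#'   scalar `auc`.
#' @export
roc_curve <- function(pmap, truth) {
  p <- if (inherits(pmap, "prob_map")) pmap$p else as.numeric(pmap)
  truth <- as.integer(truth)
  stopifnot(length(p) == length(truth), all(truth %in% c(0L, 1L)))
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes in truth", call. = FALSE)
  }
  thr <- c(Inf, sort(unique(p), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(p >= t & truth == 1L) / n_pos, 1)
  fpr <- vapply(thr, function(t) sum(p >= t & truth == 0L) / n_neg, 1)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  structure(list(curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n", nrow(x$curve), x$auc))
  invisible(x)
}

#' Full fit report for one reconstruction
#'
#' Thresholds the probability map, counts the confusion matrix and collects
#' every fit statistic: the basic rates, AUC, Cohen's kappa and both McNemar
#' variants.
#'
#' @param pmap A `prob_map` or probability vector.
#' @param truth True 0/1 element labels.
#' @param t Decision threshold (default 0.5).
#' @return One-row tibble.
#' @export
fit_report <- function(pmap, truth, t = 0.5) {
  pred <- threshold_map(pmap, t)
  counts <- confusion(pred, truth)
  auc <- tryCatch(roc_curve(pmap, truth)$auc, error = function(e) NA_real_)
  dplyr::bind_cols(
    fit_measures(counts),
    tibble::tibble(auc = auc,
                   kappa = cohens_kappa(counts),
                   mcnemar_raw = mcnemar(counts, corrected = FALSE),
                   mcnemar_corrected = mcnemar(counts, corrected = TRUE),
                   threshold = t,
                   TP = counts$TP, FP = counts$FP,
                   FN = counts$FN, TN = counts$TN)
  )
}

#' Round half-up to a number of decimals
#'
#' Table-style rounding (0.8125 -> 0.813 at 3 decimals), unlike R's
#' round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}

# Rasterization -----------------------------------------------------------

#' Rasterize per-element values onto a square pixel grid
#'
#' Overlays an N x N grid on the mesh bounding box; each pixel takes the
#' value of the element containing its center (elements are scanned in
#' increasing index, so a center on a shared edge belongs to the
#' lowest-index element); pixels outside the domain are 0.
#'
#' @param values Per-element values.
#' @param mesh A `torso_mesh`.
#' @param N Grid size (N >= 8).
#' @return A `raster_image`: N x N matrix (row = y from bottom, column = x)
#'   plus the pixel-to-physical mapping.
#' @export
rasterize <- function(values, mesh, N = 64L) {
  stopifnot(inherits(mesh, "torso_mesh"), N >= 8L,
            length(values) == nrow(mesh$elements))
  xr <- range(mesh$nodes[, 1L]); yr <- range(mesh$nodes[, 2L])
  xs <- xr[1L] + (seq_len(N) - 0.5) / N * diff(xr)
  ys <- yr[1L] + (seq_len(N) - 0.5) / N * diff(yr)
  px <- rep(xs, times = N)            # column-major over (x idx, y idx)
  py <- rep(ys, each = N)
  assign_el <- integer(N * N)
  el <- mesh$elements
  nd <- mesh$nodes
  for (e in seq_len(nrow(el))) {
    p1 <- nd[el[e, 1L], ]; p2 <- nd[el[e, 2L], ]; p3 <- nd[el[e, 3L], ]
    xmin <- min(p1[1L], p2[1L], p3[1L]); xmax <- max(p1[1L], p2[1L], p3[1L])
    ymin <- min(p1[2L], p2[2L], p3[2L]); ymax <- max(p1[2L], p2[2L], p3[2L])
    cand <- which(px >= xmin & px <= xmax & py >= ymin & py <= ymax &
                    assign_el == 0L)
    if (!length(cand)) next
    d <- 2 * mesh$element_areas[e]
    w1 <- ((p2[1L] - px[cand]) * (p3[2L] - py[cand]) -
           (p3[1L] - px[cand]) * (p2[2L] - py[cand])) / d
    w2 <- ((p3[1L] - px[cand]) * (p1[2L] - py[cand]) -
           (p1[1L] - px[cand]) * (p3[2L] - py[cand])) / d
    w3 <- 1 - w1 - w2
    inside <- w1 >= -1e-12 & w2 >= -1e-12 & w3 >= -1e-12
    assign_el[cand[inside]] <- e
  }
  img <- matrix(0, N, N)
  hit <- assign_el > 0L
  img[cbind(((which(hit) - 1L) %/% N) + 1L,       # row = y index
            ((which(hit) - 1L) %% N) + 1L)] <- values[assign_el[hit]]
  structure(list(img = img, N = N, xlim = xr, ylim = yr,
                 element = assign_el),
            class = "raster_image")
}

#' Image-quality metrics between two rasters
#'
#' MSE and MAE over all pixels, `PSNR = 10 log10(max^2 / MSE)` with `max`
#' the dynamic range of the reference image `I` (1 for binary or
#' probability images), and the global single-window SSIM with
#' `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`.
#'
#' @param I Reference `raster_image` (or matrix).
#' @param K Reconstructed `raster_image` (or matrix) of the same size.
#' @param L Dynamic-range constant for SSIM (default 1).
#' @return One-row tibble: `mse`, `mae`, `psnr` (dB, `Inf` when MSE = 0),
#'   `ssim`.
#' @export
image_quality <- function(I, K, L = 1) {
  gi <- if (inherits(I, "raster_image")) I$img else as.matrix(I)
  gk <- if (inherits(K, "raster_image")) K$img else as.matrix(K)
  if (!all(dim(gi) == dim(gk))) stop("images must have identical size", call. = FALSE)
  d <- gi - gk
  mse <- mean(d^2)
  mae <- mean(abs(d))
  rng <- diff(range(gi))
  if (rng == 0) rng <- max(abs(gi), 1)
  psnr <- if (mse == 0) Inf else 10 * log10(rng^2 / mse)
  mu_i <- mean(gi); mu_k <- mean(gk)
  v_i <- mean((gi - mu_i)^2); v_k <- mean((gk - mu_k)^2)
  cov_ik <- mean((gi - mu_i) * (gk - mu_k))
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ssim <- ((2 * mu_i * mu_k + c1) * (2 * cov_ik + c2)) /
    ((mu_i^2 + mu_k^2 + c1) * (v_i + v_k + c2))
  tibble::tibble(mse = mse, mae = mae, psnr = psnr, ssim = ssim)
}
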