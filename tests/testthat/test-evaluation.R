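test_that("thresholding is boundary-inclusive and validated", {
  expect_equal(threshold_map(c(0.2, 0.5, 0.7), 0.5), c(0L, 1L, 1L))
  expect_equal(threshold_map(c(0.2, 0.5), 0), c(1L, 1L))
  expect_error(threshold_map(c(0.2), 1.0001), "\\[0, 1\\]")
})

test_that("confusion counting matches enumeration", {
  pred <- c(1L, 0L, 1L, 1L, 0L, 0L)
  truth <- c(1L, 1L, 0L, 1L, 0L, 1L)
  cc <- confusion(pred, truth)
  expect_equal(unlist(cc[c("TP", "FP", "FN", "TN")]),
               c(TP = 2L, FP = 1L, FN = 2L, TN = 1L))
  same <- confusion(truth, truth)
  expect_equal(same$FP + same$FN, 0L)
  inv <- confusion(1L - truth, truth)
  expect_equal(inv$TP + inv$TN, 0L)
  expect_error(confusion(pred, truth[-1L]), "equal length")
})

test_that("fit-measure algebra holds on random confusion matrices", {
  set.seed(10)
  for (i in 1:200) {
    cts <- confusion_counts(sample(0:50, 1L), sample(0:50, 1L),
                            sample(0:50, 1L), sample(0:50, 1L))
    total <- cts$TP + cts$FP + cts$FN + cts$TN
    if (total == 0L) next
    fm <- fit_measures(cts)
    expect_equal(fm$accuracy * total, cts$TP + cts$TN, tolerance = 1e-12)
    if (!is.na(fm$balanced_accuracy)) {
      expect_equal(fm$balanced_accuracy,
                   (fm$sensitivity + fm$specificity) / 2, tolerance = 1e-12)
    }
    expect_gte(fm$detection_prevalence, fm$detection_rate)
    expect_equal(fm$precision, fm$pos_pred_value)
    # kappa algebraic equivalence with (p_o - p_e) / (1 - p_e)
    k <- cohens_kappa(cts)
    po <- (cts$TP + cts$TN) / total
    pe <- ((cts$TP + cts$FP) * (cts$TP + cts$FN) +
           (cts$FN + cts$TN) * (cts$FP + cts$TN)) / total^2
    if (!is.na(k) && pe < 1) {
      expect_equal(k, (po - pe) / (1 - pe), tolerance = 1e-12)
    }
  }
})

test_that("McNemar variants follow their closed forms", {
  cts <- confusion_counts(5, 8, 8, 10)
  expect_equal(mcnemar(cts), 0)                      # FP = FN
  cts2 <- confusion_counts(5, 9, 4, 10)
  expect_equal(mcnemar(cts2), 25 / 13)
  expect_equal(mcnemar(cts2, corrected = TRUE), 16 / 13)
  expect_equal(mcnemar(confusion_counts(3, 0, 0, 4)), 0)  # sentinel
})

test_that("ROC endpoints, ties and AUC match the pair-counting oracle", {
  p <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2)
  y <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L)
  expect_equal(roc_curve(p, y)$auc, 1)
  expect_equal(roc_curve(rep(0.5, 8L), y)$auc, 0.5)
  set.seed(14)
  for (i in 1:20) {
    pp <- round(stats::runif(8), 1)                  # force ties
    yy <- sample(0:1, 8L, replace = TRUE)
    if (length(unique(yy)) < 2L) next
    r <- roc_curve(pp, yy)
    expect_equal(r$auc, pair_count_auc(pp, yy), tolerance = 1e-10)
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_equal(unlist(r$curve[1L, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), c("fpr", "tpr")]),
                 c(fpr = 1, tpr = 1))
    # invariance under strictly monotone transforms
    expect_equal(roc_curve(stats::plogis(5 * pp - 2), yy)$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(p, rep(1L, 8L)), "both classes")
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  p <- stats::runif(60)
  y <- stats::rbinom(60, 1L, 0.3)
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_curve(p, y)$auc, auc_ref, tolerance = 1e-10)
})

test_that("rasterization assigns pixel centers to elements deterministically", {
  m <- unit_square_mesh(h = 0.3)
  vals <- rep(2.5, nrow(m$elements))
  r <- rasterize(vals, m, 16L)
  expect_true(all(r$img[r$element > 0L] == 2.5))
  expect_true(all(r$img[r$element == 0L] == 0))
  r0 <- rasterize(rep(0, nrow(m$elements)), m, 16L)
  expect_true(all(r0$img == 0))
  # area-sampling consistency under grid refinement
  vals2 <- seq_len(nrow(m$elements)) / nrow(m$elements)
  rA <- rasterize(vals2, m, 32L)
  rB <- rasterize(vals2, m, 64L)
  mA <- mean(rA$img[matrix(rA$element > 0L, 32L)])
  mB <- mean(rB$img[matrix(rB$element > 0L, 64L)])
  expect_equal(mA, mB, tolerance = 0.05)
  expect_error(rasterize(vals, m, 4L), "N")
})

test_that("image-quality metrics follow their closed forms", {
  set.seed(16)
  I <- matrix(stats::rbinom(256, 1L, 0.3), 16L)
  q <- image_quality(I, I)
  expect_equal(q$mse, 0); expect_equal(q$mae, 0)
  expect_equal(q$ssim, 1); expect_equal(q$psnr, Inf)
  # q-pixel-differing binary images
  K <- I; flip <- sample(256, 13L); K[flip] <- 1L - K[flip]
  q2 <- image_quality(I, K)
  expect_equal(q2$mse, 13 / 256)
  expect_equal(q2$mae, 13 / 256)
  # PSNR closed form
  J <- matrix(0, 10L, 10L); J[1L] <- 1       # dynamic range 1
  K2 <- J; K2[2:2] <- K2[2] + sqrt(0.01 * 100 / 99)  # make MSE = 0.01
  K2 <- J + sqrt(0.01)                        # uniform offset: MSE exactly 0.01
  q3 <- image_quality(J, K2)
  expect_equal(q3$mse, 0.01, tolerance = 1e-12)
  expect_equal(q3$psnr, 20, tolerance = 1e-10)
  # SSIM symmetry and bound; PSNR decreasing in MSE
  A <- matrix(stats::runif(64), 8L); B <- matrix(stats::runif(64), 8L)
  expect_equal(image_quality(A, B, L = 1)$ssim,
               image_quality(B, A, L = 1)$ssim, tolerance = 1e-12)
  expect_lte(image_quality(A, B)$ssim, 1)
  expect_gt(image_quality(J, J + sqrt(0.005))$psnr, q3$psnr)
})

test_that("fit_report collects rates, AUC, kappa and both McNemar forms", {
  set.seed(17)
  p <- stats::runif(100)
  y <- stats::rbinom(100, 1L, p)               # informative probabilities
  rep <- fit_report(p, y, t = 0.5)
  cts <- confusion(threshold_map(p, 0.5), y)
  expect_equal(rep$kappa, cohens_kappa(cts))
  expect_equal(rep$mcnemar_raw, mcnemar(cts))
  expect_equal(rep$mcnemar_corrected, mcnemar(cts, corrected = TRUE))
  expect_equal(rep$auc, roc_curve(p, y)$auc)
  expect_equal(rep$TP + rep$FP + rep$FN + rep$TN, 100)
})

test_that("half-up rounding matches table conventions", {
  expect_equal(round_half_up(0.8125), 0.813)  # R's round() would give 0.812
  expect_equal(round_half_up(812.5, 0), 813)
  expect_equal(round_half_up(-0.8125), -0.813)
})
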