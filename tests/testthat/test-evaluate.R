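test_that("Otsu binarization matches an exhaustive search oracle", {
  # two-delta histogram: threshold strictly between the modes
  pm <- matrix(rep(c(0.1, 0.9), each = 32), 8)
  o <- binarize_otsu(pm)
  expect_gt(o$threshold, 0.1)
  expect_lt(o$threshold, 0.9)
  expect_identical(o$mask, pm > 0.5)

  # random map: equality with an independent 256-level search
  set.seed(60)
  pm <- matrix(runif(64 * 64), 64)
  o <- binarize_otsu(pm)
  bins <- pmin(floor(pm * 256) + 1, 256)
  counts <- tabulate(bins, 256)
  best <- -Inf; best_k <- NA
  for (k in 1:255) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mids <- (1:256 - 0.5) / 256
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) { best <- v; best_k <- k }
  }
  expect_equal(o$threshold, best_k / 256)
  # and agreement with EBImage to one histogram bin
  expect_lt(abs(o$threshold - EBImage::otsu(pm, range = c(0, 1),
                                            levels = 256)), 1 / 256)

  # a {0,1} map binarizes to itself; constant maps warn
  mm <- matrix(rep(c(0, 1), 32), 8)
  expect_identical(binarize_otsu(mm)$mask, mm == 1)
  expect_warning(cb <- binarize_otsu(matrix(0.4, 4, 4)), "constant")
  expect_false(any(cb$mask))
})

test_that("post-processing applies the three clean-up rules", {
  border <- matrix(TRUE, 40, 40)
  mask <- matrix(FALSE, 40, 40)
  mask[2:8, 2:8] <- TRUE               # 49 pixels
  mask[20:29, 31:35] <- TRUE           # 50 pixels
  out <- postprocess_mask(mask, border, min_area = 50)
  expect_identical(sum(out), 50L)
  expect_false(any(out[2:8, 2:8]))

  bg <- matrix(FALSE, 40, 40); bg[20:24, 31:35] <- TRUE
  out2 <- postprocess_mask(mask, border, bg, min_area = 10)
  expect_false(any(out2 & bg))

  empty <- matrix(FALSE, 40, 40)
  expect_identical(sum(postprocess_mask(empty, border)), 0L)

  # border rule and 8-connectivity: a diagonal chain is one component
  diagm <- matrix(FALSE, 40, 40)
  diagm[cbind(5:24, 5:24)] <- TRUE
  expect_identical(sum(postprocess_mask(diagm, border, min_area = 20)),
                   20L)
  nb <- border; nb[, 1:10] <- FALSE
  expect_false(any(postprocess_mask(diagm, nb, min_area = 1)[, 1:10]))
})

test_that("segmentation metrics follow the printed formulas", {
  border <- matrix(TRUE, 10, 10)
  truth <- matrix(FALSE, 10, 10); truth[1:10] <- TRUE
  m <- seg_metrics(truth, truth, border)
  expect_equal(unlist(m[c("precision", "sensitivity", "specificity",
                          "f1", "iou")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 f1 = 1, iou = 1))

  # TP=8, FP=2, FN=2, TN=88
  pred <- matrix(FALSE, 10, 10)
  pred[1:8] <- TRUE; pred[11:12] <- TRUE
  m <- seg_metrics(pred, truth, border)
  expect_equal(m$precision, 0.8)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 88 / 90, tolerance = 1e-4)
  expect_equal(m$f1, 0.8)
  expect_equal(m$iou, 8 / 12, tolerance = 1e-4)

  comp <- seg_metrics(!truth, truth, border)
  expect_equal(comp$sensitivity, 0)
  expect_equal(comp$precision, 0)

  # undefined metrics are NA, not zero
  none <- matrix(FALSE, 10, 10)
  m2 <- seg_metrics(none, none, border)
  expect_true(is.na(m2$precision))
  expect_true(is.na(m2$sensitivity))

  # F1 = 2 IoU / (1 + IoU) on random masks
  for (s in 1:5) {
    set.seed(s)
    p <- matrix(runif(100) < 0.3, 10)
    t <- matrix(runif(100) < 0.3, 10)
    mm <- seg_metrics(p, t, border)
    if (!is.na(mm$f1))
      expect_equal(mm$f1, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-12)
  }
})

test_that("AUROC equals the rank statistic", {
  expect_equal(auroc(c(3, 4, 5, 0, 1, 2), c(1, 1, 1, 0, 0, 0)), 1)
  expect_equal(auroc(c(.9, .8, .4, .7, .3, .1), c(1, 1, 1, 0, 0, 0)),
               8 / 9)
  set.seed(61)
  s <- runif(20000); l <- rbinom(20000, 1, 0.5)
  expect_lt(abs(auroc(s, l) - 0.5), 0.02)
  expect_warning(v <- auroc(runif(5), rep(1, 5)), "single-class")
  expect_true(is.na(v))
  # ties credited one half
  expect_equal(auroc(c(1, 1), c(1, 0)), 0.5)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(62)
  x <- matrix(rnorm(600 * 4), ncol = 4,
              dimnames = list(NULL, c("signal", "noise1", "noise2",
                                      "const")))
  x[, "const"] <- 1
  y <- as.integer(x[, "signal"] > 0)
  m <- fit_vessel_model(x, y, config = list(learning_rate = 0.1,
                                            n_stages = 50L,
                                            max_depth = 3L))
  imp <- permutation_importance(m, x, y, repeats = 10, seed = 9)
  expect_identical(nrow(imp), 4L)
  expect_identical(attr(imp, "repeats"), 10L)
  expect_equal(imp$importance[imp$feature == "const"], 0)
  expect_gt(imp$importance[imp$feature == "signal"],
            max(imp$importance[imp$feature != "signal"]))

  imp2 <- permutation_importance(m, x, y, repeats = 10, seed = 9)
  expect_identical(imp, imp2)
  expect_error(permutation_importance(m, x, y, repeats = 0), "repeats")
})
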