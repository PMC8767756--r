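ss6 <- build_scale_set(6, 6)

test_that("Frangi Z-profile lights up tube centerlines, not blobs", {
  const <- matrix(0.5, 48, 48)
  zp <- frangi_zprofile(const, ss6)
  expect_equal(max(abs(zp$z_max)), 0)

  tube <- tube_image(64, width = 6)
  zp <- frangi_zprofile(tube, ss6)
  mid <- 20:44
  expect_gt(mean(zp$z_max[mid, 32:33]), mean(zp$z_max[mid, 1:10]))
  # response-vs-scale argmax near w/2 for centerline pixels
  resp <- sapply(ss6$scales, function(lam) {
    e <- vesselforge:::hessian_eigen(
      vesselforge:::hessian_at_scale(tube, lam / 2))
    mean(vesselforge:::frangi_response(e)[mid, 32])
  })
  best_sigma <- ss6$scales[which.max(resp)] / 2
  expect_lt(abs(best_sigma - 3), 2.5)

  # isotropic blob of matched contrast scores below the tube
  blob <- matrix(0.8, 64, 64)
  dd <- (row(blob) - 32)^2 + (col(blob) - 32)^2
  blob <- blob - 0.3 * exp(-dd / (2 * (6 / 2.355)^2))
  zb <- frangi_zprofile(blob, ss6)
  expect_lt(zb$z_max[32, 32], zp$z_max[32, 32])
})

test_that("matched filter responds at the bar orientation and scale", {
  const <- matrix(0.5, 40, 40)
  expect_lt(max(abs(matched_filter_zprofile(const, ss6)$z_max)), 1e-8)

  # dark bar whose cross-section coordinate sits at 30 degrees, the same
  # parameterization the kernel bank uses
  size <- 81
  theta <- 30 * pi / 180
  rr <- row(matrix(0, size, size)) - 41
  cc <- col(matrix(0, size, size)) - 41
  u <- cc * cos(theta) + rr * sin(theta)
  bar <- 0.8 - 0.4 * exp(-u^2 / (2 * 2^2))
  kers <- vesselforge:::matched_filter_kernels(6, 12)
  resp <- vapply(kers, function(k)
    vesselforge:::ff2(bar, k)[41, 41], numeric(1))
  angles <- (seq_len(12) - 1) * 15
  best <- angles[which.max(resp)]
  dist30 <- min(abs(best - 30), 180 - abs(best - 30))
  expect_lte(dist30, 15)

  # matched scale beats a 4x larger scale on the same (finite) bar
  v <- -cc * sin(theta) + rr * cos(theta)
  fbar <- 0.8 - 0.4 * exp(-u^2 / (2 * 2^2)) * exp(-v^2 / (2 * 8^2))
  k30 <- function(lam) vesselforge:::matched_filter_kernels(lam, 12)[[3]]
  small <- max(vesselforge:::ff2(fbar, k30(5)))
  large <- max(vesselforge:::ff2(fbar, k30(20)))
  expect_gt(small, large)
})

test_that("smoothed gradient magnitude matches the Gaussian step closed form", {
  const <- matrix(0.5, 40, 40)
  expect_equal(max(abs(gradient_magnitude_zprofile(const, ss6)$z_max)), 0,
               tolerance = 1e-10)

  step <- matrix(0, 64, 64); step[, 33:64] <- 1
  ss2 <- build_scale_set(8, 2)
  zp <- gradient_magnitude_zprofile(step, ss2)
  sigma <- ss2$scales[1] / 2
  analytic <- 1 / (sigma * sqrt(2 * pi))
  expect_lt(abs(max(zp$z_max[32, ]) - analytic) / analytic, 0.05)

  # 90-degree rotation equivariance (exact on the pixel grid)
  set.seed(8)
  img <- matrix(runif(48 * 48), 48)
  z1 <- gradient_magnitude_zprofile(img, ss6)$z_max
  rot <- t(img)[, 48:1]
  z2 <- gradient_magnitude_zprofile(rot, ss6)$z_max
  expect_equal(z2, t(z1)[, 48:1], tolerance = 1e-6)
})

test_that("vessel confidence scores tubes above flat and noisy fields", {
  const <- matrix(0.5, 40, 40)
  expect_lt(max(vessel_confidence(const, ss6)), 1e-6)

  tube <- tube_image(64, width = 6)
  conf <- vessel_confidence(tube, ss6)
  expect_true(all(conf >= 0 & conf <= 1))
  mid <- 20:44
  expect_gt(mean(conf[mid, 32]), 0.5)
  expect_gt(mean(conf[mid, 32]), mean(conf[mid, 1:10]))

  set.seed(9)
  noise <- matrix(runif(64 * 64), 64)
  expect_lt(mean(vessel_confidence(noise, ss6)),
            mean(conf[mid, 30:34]))
})

test_that("granulometric residues localize size classes", {
  const <- matrix(0.4, 40, 40)
  expect_equal(max(abs(granular_zprofile(const, ss6)$z_max)), 0)

  # bright disk of diameter 9: residue mass concentrates at the first
  # scale >= 9 (oracle: explicit openings per scale)
  img <- matrix(0.1, 64, 64)
  dd <- sqrt((row(img) - 32)^2 + (col(img) - 32)^2)
  img[dd <= 4.5] <- 0.9
  ss <- build_scale_set(3, 5)  # scales 1.98 .. 18.99
  prev <- img
  mass <- vapply(ss$scales, function(lam) {
    op <- EBImage::opening(img, vesselforge:::disc_brush(lam))
    m <- sum(prev - op)
    prev <<- op
    m
  }, numeric(1))
  expect_equal(which.max(mass), min(which(ss$scales >= 9)))

  # anti-extensivity chain: total residue mass cannot exceed image mass
  set.seed(10)
  rnd <- matrix(runif(32 * 32), 32)
  zp <- granular_zprofile(rnd, ss6)
  total <- zp$z_mean * ss6$n_scales  # sum of residues per pixel
  expect_lte(sum(total), sum(rnd) + 1e-9)
  expect_true(all(total >= -1e-9))
})

test_that("Gabor bank is orientation-selective, zero-DC and linear", {
  const <- matrix(0.5, 40, 40)
  expect_lt(max(abs(gabor_zprofile(const, ss6)$z_max)), 1e-8)

  # bright bar (complement space) with cross-section coordinate at 45 deg
  size <- 81
  rr <- row(matrix(0, size, size)) - 41
  cc <- col(matrix(0, size, size)) - 41
  u <- (cc + rr) / sqrt(2)
  bar <- 0.6 * exp(-u^2 / (2 * 2^2))
  best_by_orient <- vapply(seq_len(12), function(k) {
    ker <- vesselforge:::gabor_kernel(8, (k - 1) * pi / 12, 0.56 * 8)
    vesselforge:::ff2(bar, ker)[41, 41]
  }, numeric(1))
  best <- (which.max(best_by_orient) - 1) * 15
  expect_lte(min(abs(best - 45), 180 - abs(best - 45)), 15)

  z1 <- gabor_zprofile(bar, ss6)
  z2 <- gabor_zprofile(2 * bar, ss6)
  expect_equal(z2$z_max, 2 * z1$z_max, tolerance = 1e-6)
})

test_that("stack assembly enforces the 21/37 bookkeeping", {
  mk <- function() zprofile(array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  set.seed(11)
  conf <- matrix(runif(64), 8)
  stack21 <- assemble_stack(mk(), mk(), mk(), conf, mk(), mk())
  expect_length(stack21$maps, 21)
  expect_false(anyDuplicated(stack21$names) > 0)

  deep <- lapply(1:16, function(i) matrix(rnorm(64), 8))
  stack37 <- assemble_stack(mk(), mk(), mk(), conf, mk(), mk(), deep)
  expect_length(stack37$maps, 37)
  differentiable <- grepl("^(frangi|matched|gradient|confidence)",
                          stack37$names)
  expect_identical(sum(differentiable), 13L)
  expect_identical(sum(grepl("^deep", stack37$names)), 16L)
  expect_identical(sum(grepl("^granular", stack37$names)), 4L)
  expect_identical(sum(grepl("^gabor", stack37$names)), 4L)

  bad <- lapply(1:16, function(i) matrix(0, 4, 4))
  expect_error(assemble_stack(mk(), mk(), mk(), conf, mk(), mk(), bad),
               "shape")
})

test_that("standardization fits on train and transforms test unchanged", {
  mk <- function() zprofile(array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  set.seed(12)
  stack <- assemble_stack(mk(), mk(), mk(), matrix(runif(64), 8),
                          mk(), mk())
  fitted <- standardize(stack)
  for (m in fitted$maps) {
    expect_lt(abs(mean(m)), 1e-6)
    expect_lt(abs(sd(m) - 1), 1e-6)
  }

  # constant map collapses to zeros with a warning
  stack$maps[[1]] <- matrix(5, 8, 8)
  expect_warning(fitted2 <- standardize(stack), "zero-variance")
  expect_equal(max(abs(fitted2$maps[[1]])), 0)

  # transform mode applies saved parameters verbatim: (10 - 2) / 4 = 2
  params <- fitted$standardization
  params[[1]] <- list(mean = 2, sd = 4)
  stack$maps[[1]] <- matrix(10, 8, 8)
  out <- standardize(stack, params)
  expect_equal(out$maps[[1]][1, 1], 2.0)
  # round trip: transform mode never re-estimates
  expect_identical(out$standardization, params)
})

test_that("vessel features separate tube from background on a clean render", {
  pair <- quiet_pair(6, canvas = c(96, 96), cath_px = 5)
  img <- pair$angiogram$pixels
  ss <- build_scale_set(5, 6)
  vm <- pair$mask$labels & pair$angiogram$border_mask
  bg <- !pair$mask$labels & pair$angiogram$border_mask
  for (zp in list(frangi_zprofile(img, ss),
                  matched_filter_zprofile(img, ss),
                  gabor_zprofile(1 - img, ss)))
    expect_gt(mean(zp$z_max[vm]), mean(zp$z_max[bg]))
})
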