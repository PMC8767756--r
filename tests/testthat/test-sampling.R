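test_that("uniform under-sampling yields an 8-neighborhood independent set", {
  neg <- matrix(TRUE, 4, 4)
  border <- matrix(TRUE, 4, 4)
  got <- uniform_undersample(neg, border)
  expect_identical(nrow(got), 4L)
  # exhaustive pair check: Chebyshev distance >= 2
  for (i in seq_len(nrow(got) - 1)) for (j in (i + 1):nrow(got))
    expect_gte(max(abs(got[i, ] - got[j, ])), 2)

  empty <- matrix(FALSE, 4, 4)
  expect_identical(nrow(uniform_undersample(empty, border)), 0L)

  # density bound on a large all-negative frame, any offset
  big <- matrix(TRUE, 64, 64)
  for (off in list(c(0L, 0L), c(1L, 0L), c(1L, 1L))) {
    got <- uniform_undersample(big, big, offset = off)
    expect_lte(nrow(got) / 64^2, 0.25)
    dr <- outer(got[, 1], got[, 1], "-")
    dc <- outer(got[, 2], got[, 2], "-")
    cheb <- pmax(abs(dr), abs(dc))
    diag(cheb) <- Inf
    expect_gte(min(cheb), 2)
  }
})

test_that("intensity-based under-sampling removes the bright background", {
  # bimodal: dark tube ~0.2, bright background ~0.9
  img <- matrix(0.9, 64, 64)
  img[, 30:34] <- 0.2
  border <- matrix(TRUE, 64, 64)
  neg <- img > 0.5
  negc <- which(neg, arr.ind = TRUE)
  got <- unsupervised_undersample(img, negc, border)
  expect_gte(got$threshold, 0.2)
  expect_lt(got$threshold, 0.9)
  expect_identical(nrow(got$kept), 0L)  # all bright negatives removed
  dark_negs <- cbind(5:10, 30L)
  got2 <- unsupervised_undersample(img, dark_negs, border)
  expect_identical(nrow(got2$kept), length(5:10))  # dark ones survive
  expect_true(all(got$removal_mask[img > got$threshold]))

  # saturated spike: 30% of pixels at the top bin
  set.seed(30)
  v <- runif(64 * 64, 0, 0.8)
  v[seq_len(round(0.3 * 64 * 64))] <- 0.999
  img2 <- matrix(v, 64)
  got3 <- unsupervised_undersample(img2, negc, border)
  expect_identical(got3$peak_bin, 256L)
  expect_equal(got3$threshold,
               median(v[floor(v * 256) + 1 != 256]),
               tolerance = 1e-12)

  # degenerate single intensity keeps everything
  expect_warning(
    got4 <- unsupervised_undersample(matrix(0.5, 8, 8),
                                     cbind(1:3, 1:3),
                                     matrix(TRUE, 8, 8)),
    "degenerate")
  expect_identical(nrow(got4$kept), 3L)
  expect_false(any(got4$removal_mask))
})

test_that("Tomek-link removal matches a brute-force oracle", {
  # 1-D example: the (0.0, 0.1) cross-class pair is a link
  ds <- pixel_dataset(matrix(c(0, 0.1, 5), ncol = 1,
                             dimnames = list(NULL, "f")),
                      c(1, 0, 0))
  out <- tomek_links(ds)
  expect_identical(nrow(out$features), 1L)
  expect_equal(unname(out$features[1, 1]), 5)

  # perfectly separated clusters: identity
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0, 0.1), ncol = 2),
             matrix(rnorm(40, 10, 0.1), ncol = 2))
  colnames(x) <- c("a", "b")
  ds <- pixel_dataset(x, rep(c(1, 0), each = 20))
  expect_identical(nrow(tomek_links(ds)$features), 40L)

  # 200 random points: equivalence with the O(N^2) oracle
  set.seed(32)
  x <- matrix(rnorm(400), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- rbinom(200, 1, 0.5)
  ds <- pixel_dataset(x, y)
  out <- tomek_links(ds)
  keep <- brute_tomek_keep(x, y)
  expect_identical(out$features, x[keep, , drop = FALSE])
  expect_identical(out$labels, as.integer(y[keep]))

  # subset + idempotence: a second pass removes nothing
  again <- tomek_links(out)
  expect_identical(again$features, out$features)

  one <- pixel_dataset(x, rep(1L, 200))
  expect_warning(same <- tomek_links(one), "single-class")
  expect_identical(nrow(same$features), 200L)
})

test_that("cluster-centroid under-sampling balances classes exactly", {
  set.seed(33)
  # two tight blobs per class
  mk_blob <- function(mu, n) cbind(rnorm(n, mu[1], 0.05),
                                   rnorm(n, mu[2], 0.05))
  xp <- rbind(mk_blob(c(0, 0), 100), mk_blob(c(2, 2), 100))
  xn <- rbind(mk_blob(c(5, 0), 100), mk_blob(c(7, 2), 100))
  x <- rbind(xp, xn); colnames(x) <- c("a", "b")
  ds <- pixel_dataset(x, rep(c(1, 0), each = 200))
  out <- cluster_centroid(ds, 2, seed = 1)
  expect_identical(nrow(out$features), 4L)
  expect_equal(mean(out$labels), 0.5)
  # centroid recovery within 3 sigma / sqrt(n) of the true blob means
  tol <- 3 * 0.05 / sqrt(100)
  pos_ctr <- out$features[out$labels == 1, , drop = FALSE]
  for (mu in list(c(0, 0), c(2, 2))) {
    d <- sqrt(colSums((t(pos_ctr) - mu)^2))
    expect_lt(min(d), tol * sqrt(2) + 0.02)
  }

  # target equal to the class size returns the points themselves
  small <- pixel_dataset(x[c(1:5, 201:205), ], rep(c(1, 0), each = 5))
  idq <- cluster_centroid(small, 5)
  expect_identical(sort(idq$features[idq$labels == 1, 1]),
                   sort(x[1:5, 1]))

  # over-large target keeps that class's points with a warning
  lop <- pixel_dataset(x[c(1:5, 201:208), ], c(rep(1, 5), rep(0, 8)))
  expect_warning(keep_all <- cluster_centroid(lop, 7), "fewer")
  expect_identical(nrow(keep_all$features), 12L)

  # balance holds regardless of input imbalance
  imb <- pixel_dataset(x, c(rep(1, 30), rep(0, 370)))
  bal <- cluster_centroid(imb, 10, seed = 2)
  expect_equal(mean(bal$labels), 0.5)
  expect_identical(nrow(bal$features), 20L)
  expect_null(bal$origin)
})

test_that("the cascade never drops positives early and stays in-border", {
  pair <- quiet_pair(40, canvas = c(96, 96), cath_px = 5,
                     noise_sigma = 0.02, confounders = TRUE)
  ss <- build_scale_set(5, 4)
  enh <- top_bottom_hat_enhance(pair$angiogram$pixels, ss)
  stack <- assemble_stack(
    frangi_zprofile(pair$angiogram$pixels, ss),
    matched_filter_zprofile(pair$angiogram$pixels, ss),
    gradient_magnitude_zprofile(pair$angiogram$pixels, ss),
    vessel_confidence(pair$angiogram$pixels, ss),
    granular_zprofile(enh, ss),
    gabor_zprofile(1 - enh$pixels, ss))
  ds <- extract_pixels(standardize(stack), pair$mask,
                       pair$angiogram$border_mask, "imgA")
  res <- run_sampling_cascade(ds, enh, pair$angiogram$border_mask,
                              stages = c("uniform", "unsupervised",
                                         "tomek", "centroid"),
                              per_class = 50, image_id = "imgA")
  n_pos_raw <- sum(ds$labels == 1)
  expect_identical(sum(res$stages$uniform$labels == 1), n_pos_raw)
  expect_identical(sum(res$stages$unsupervised$labels == 1), n_pos_raw)
  expect_identical(nrow(res$dataset$features), 100L)
  expect_equal(mean(res$dataset$labels), 0.5)
  for (nm in c("raw", "uniform", "unsupervised", "tomek")) {
    org <- res$stages[[nm]]$origin
    expect_true(all(pair$angiogram$border_mask[as.matrix(
      org[, c("row", "col")])]))
  }

  rep <- build_report(res$stages)
  expect_true(all(diff(rep$total) <= 0))
  expect_equal(rep$positive_pct + rep$negative_pct, rep(100, nrow(rep)))
  # percentages recomputed from counts agree at report precision (3 decimals)
  pos_counts <- vapply(res$stages, function(d) sum(d$labels == 1),
                       numeric(1))
  expect_equal(round(rep$positive_pct, 3),
               round(unname(100 * pos_counts / rep$total), 3))
})
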