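meta130 <- data.frame(id = sprintf("im%03d", 1:130),
                      view_label = rep(c("LCA", "RCA"), c(80, 50)),
                      source = "ds1")

test_that("stratified splits honour the 4:1 and 3:1:1 arithmetic", {
  sp <- make_split(meta130, mode = "ensemble", seed = 3)
  expect_identical(sum(sp$set == "train"), 104L)
  expect_identical(sum(sp$set == "test"), 26L)
  # stratum proportions within one image of the target ratio
  for (v in c("LCA", "RCA")) {
    n <- sum(meta130$view_label == v)
    expect_lte(abs(sum(sp$set == "test" & sp$view_label == v) - n / 5), 1)
  }

  sp3 <- make_split(meta130, mode = "deep", seed = 3)
  expect_identical(as.vector(table(sp3$set)[c("train", "validation",
                                              "test")]),
                   c(78L, 26L, 26L))

  # ensemble test set reuses the deep-learning test images
  expect_setequal(sp$id[sp$set == "test"], sp3$id[sp3$set == "test"])

  sp2 <- make_split(meta130, mode = "ensemble", seed = 3)
  expect_identical(sp, sp2)
  sp4 <- make_split(meta130, mode = "ensemble", seed = 4)
  expect_false(identical(sp$set, sp4$set))

  # image-level disjointness
  expect_false(any(sp$id[sp$set == "train"] %in% sp$id[sp$set == "test"]))
})

make_planted_datasets <- function(n_images = 8, n = 60, d = 4, seed = 50,
                                  xor = FALSE) {
  set.seed(seed)
  stats::setNames(lapply(seq_len(n_images), function(i) {
    x <- matrix(rnorm(n * d), n, d,
                dimnames = list(NULL, paste0("f", seq_len(d))))
    y <- if (xor) as.integer(xor(x[, 1] > 0, x[, 2] > 0))
         else as.integer(x[, 1] + 0.3 * rnorm(n) > 0)
    pixel_dataset(x, y, stage = "toy")
  }), paste0("img", seq_len(n_images)))
}

test_that("cross-validated tuning counts fits and finds needed capacity", {
  ds <- make_planted_datasets()
  g1 <- data.frame(learning_rate = 0.1, n_stages = 20L, max_depth = 3L)
  got <- tune_gbdt(ds, grid = g1, seed = 1)
  expect_identical(got$n_fits, 4L)
  expect_identical(got$config$max_depth, 3L)

  # the full tuning grid is 3 x 4 x 4 = 48 configurations x 4 folds
  expect_identical(nrow(vesselforge:::default_gbdt_grid()), 48L)
  g2 <- expand.grid(learning_rate = c(0.05, 0.1), n_stages = 20L,
                    max_depth = c(1L, 6L))
  got2 <- tune_gbdt(ds, grid = g2, seed = 1)
  expect_identical(got2$n_fits, nrow(g2) * 4L)

  # an XOR interaction is unlearnable at depth 1 but easy when deeper
  dsx <- make_planted_datasets(xor = TRUE, seed = 51)
  gotx <- tune_gbdt(dsx, grid = g2, seed = 1)
  expect_identical(gotx$config$max_depth, 6L)
  expect_error(tune_gbdt(ds, grid = g1[0, ]), "empty")
})

test_that("GBDT fitting separates separable toys and nothing else", {
  set.seed(52)
  x <- rbind(matrix(rnorm(100, 0), ncol = 2),
             matrix(rnorm(100, 4), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(0L, 1L), each = 50)
  m <- fit_vessel_model(x, y, method = "gbdt")
  expect_identical(as.integer(predict(m, x) > 0.5), y)

  # label noise: held-out AUROC hovers at chance
  set.seed(53)
  xn <- matrix(rnorm(2000 * 3), ncol = 3,
               dimnames = list(NULL, c("f1", "f2", "f3")))
  yn <- rbinom(2000, 1, 0.5)
  mtr <- fit_vessel_model(xn[1:1000, ], yn[1:1000],
                          config = list(learning_rate = 0.1,
                                        n_stages = 30L, max_depth = 3L))
  expect_lt(abs(auroc(predict(mtr, xn[1001:2000, ]), yn[1001:2000]) - 0.5),
            0.05)
  expect_error(fit_vessel_model(x, rep(1L, 100)), "single-class")
})

test_that("cascade forest grows bounded layers with augmented features", {
  set.seed(54)
  x <- rbind(matrix(rnorm(120, 0), ncol = 2),
             matrix(rnorm(120, 3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(0L, 1L), each = 60)
  m <- fit_deep_forest(x, y, seed = 2)
  expect_s3_class(m, "vessel_deep_forest")
  expect_identical(as.integer(predict(m, x) > 0.5), y)
  nl <- m$config$n_layers
  expect_gte(nl, 1L)
  expect_lte(nl, m$config$max_layers)
  # layer k > 1 consumes D + 2 x (forests per layer) columns
  if (nl > 1) {
    expect_identical(
      as.integer(m$fitted$layers[[2]][[1]]$num.independent.variables),
      ncol(x) + 2L * 4L)
  }
  p <- predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("stack prediction verifies manifests and zeroes the border", {
  set.seed(55)
  mkzp <- function() zprofile(array(rnorm(10 * 10 * 3), c(10, 10, 3)))
  stack <- assemble_stack(mkzp(), mkzp(), mkzp(), matrix(runif(100), 10),
                          mkzp(), mkzp())
  border <- matrix(TRUE, 10, 10); border[1, ] <- FALSE
  std <- standardize(stack)
  x <- feature_matrix(std)
  y <- as.integer(x[, "frangi.z_max"] > 0)  # planted on feature 1
  m <- fit_vessel_model(x, y, standardization = std$standardization)
  pm <- predict(m, stack, border)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(pm[1, ] == 0))
  # probabilities monotone in the planted feature
  ord <- order(x[, "frangi.z_max"])
  pv <- predict(m, x)
  expect_gt(mean(pv[tail(ord, 30)]), mean(pv[head(ord, 30)]))

  bad <- stack
  bad$names <- rev(bad$names)
  expect_error(predict(m, bad, border), "manifest")
})

test_that("fold standardization never leaks validation statistics", {
  ds <- make_planted_datasets(n_images = 4, seed = 56)
  # shift one image far away; its fold's training stats must ignore it
  ds[[1]]$features <- ds[[1]]$features + 100
  # manual audit replicating the tuning fold construction
  set.seed(1)
  ids <- names(ds)[sample.int(4)]
  blocks <- split(ids, cut(seq_along(ids), 4, labels = FALSE))
  k <- which(vapply(blocks, function(b) "img1" %in% b, logical(1)))
  tr <- pool_datasets(ds[setdiff(ids, blocks[[k]])])
  std <- fit_standardization(tr$features)
  mus <- vapply(std, `[[`, numeric(1), "mean")
  expect_true(all(abs(mus) < 5))  # untouched by the shifted image
})
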