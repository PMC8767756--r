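# shared fixtures: small synthetic pairs and analytic test images

quiet_pair <- function(seed, canvas = c(96, 96), cath_px = 4,
                       noise_sigma = 0, confounders = FALSE, ...) {
  cf <- if (confounders)
    list(catheter = TRUE, spine_bands = TRUE,
         illumination_gradient = TRUE)
  else
    list(catheter = FALSE, spine_bands = FALSE,
         illumination_gradient = FALSE)
  cfg <- synth_config(seed = seed, canvas = canvas, cath_px = cath_px,
                      noise_sigma = noise_sigma, confounders = cf, ...)
  render_angiogram(generate_vessel_tree(cfg), cfg)
}

# vertical dark tube of Gaussian cross-section, FWHM = width, on a bright
# constant field
tube_image <- function(size = 64, width = 6, depth = 0.3, bg = 0.8,
                       center = NULL) {
  if (is.null(center)) center <- (size + 1) / 2
  sigma <- width / 2.355
  img <- matrix(bg, size, size)
  for (cc in seq_len(size))
    img[, cc] <- bg - depth * exp(-(cc - center)^2 / (2 * sigma^2))
  img
}

# brute-force flat grayscale erosion/dilation/opening/closing with an
# arbitrary structuring element, replicate boundary (independent oracle)
brute_erode <- function(img, se) {
  d <- dim(img); k <- dim(se); kh <- (k - 1L) %/% 2L
  out <- img
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    vals <- c()
    for (a in seq_len(k[1])) for (b in seq_len(k[2])) {
      if (se[a, b] == 0) next
      r <- min(max(i + a - 1L - kh[1], 1L), d[1])
      cc <- min(max(j + b - 1L - kh[2], 1L), d[2])
      vals <- c(vals, img[r, cc])
    }
    out[i, j] <- min(vals)
  }
  out
}

brute_dilate <- function(img, se) -brute_erode(-img, se)
brute_open <- function(img, se) brute_dilate(brute_erode(img, se), se)
brute_close <- function(img, se) brute_erode(brute_dilate(img, se), se)

# O(N^2) Tomek-link remover, iterated to exhaustion (independent oracle)
brute_tomek_keep <- function(x, y, iterate = TRUE) {
  keep <- rep(TRUE, nrow(x))
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    dm <- as.matrix(stats::dist(x[act, , drop = FALSE]))
    diag(dm) <- Inf
    nn <- apply(dm, 1, which.min)
    link <- which(seq_along(act) < nn & nn[nn] == seq_along(act) &
                    y[act] != y[act[nn]])
    if (!length(link)) break
    keep[c(act[link], act[nn[link]])] <- FALSE
    if (!iterate) break
  }
  keep
}

random_pixel_dataset <- function(n, d = 2, seed = 1, pos_frac = 0.4) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  y <- as.integer(runif(n) < pos_frac)
  y[1] <- 1L; y[2] <- 0L
  pixel_dataset(x, y, stage = "test")
}
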