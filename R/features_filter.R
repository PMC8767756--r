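# Frangi dark-ridge vesselness from a Hessian eigen field; the structural
# constant is tied to the per-image maximum Hessian norm (half of it)
frangi_response <- function(e, beta = 0.5) {
  s2 <- e$l1^2 + e$l2^2
  c2 <- max(s2) / 4  # (max(S)/2)^2
  if (c2 <= 0) return(matrix(0, nrow(e$l1), ncol(e$l1)))
  rb2 <- (e$l1 / pmax(abs(e$l2), 1e-12))^2
  v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * c2)))
  v[e$l2 <= 0] <- 0  # dark vessels: positive curvature across the ridge
  v
}

#' Z-profile of Frangi vesselness responses
#'
#' Hessian-based tubularity: at each scale `l` the Hessian is computed at
#' Gaussian sigma `l / 2` (gamma = 2 scale normalization), its eigenvalues
#' give the blobness ratio and second-order structureness, and the Frangi
#' response is taken with dark-vessel polarity (vessels attenuate X-rays).
#'
#' @param img preprocessed intensity matrix.
#' @param scale_set a [build_scale_set()] result.
#' @param beta blobness sensitivity (default 0.5).
#' @return a [zprofile()] over the per-scale vesselness maps.
#' @export
frangi_zprofile <- function(img, scale_set, beta = 0.5) {
  ctx <- conv_ctx(img, hessian_pad(scale_set))
  resp <- lapply(scale_set$scales, function(lam) {
    e <- hessian_eigen(hessian_at_scale(img, lam / 2, ctx))
    frangi_response(e, beta)
  })
  zprofile(resp, "frangi")
}

hessian_pad <- function(scale_set)
  rep(ceiling(3 * max(scale_set$scales) / 2) + 2L, 2L)

# oriented matched-filter kernels: negated Gaussian cross-profile of width
# sigma = lambda/3 swept along a segment of length 3*lambda, zero-mean over
# the support so flat regions give no response
matched_filter_kernels <- function(lambda, n_orient = 12L) {
  sigma <- lambda / 3
  len <- 3 * lambda
  half <- ceiling(max(len / 2, 3 * sigma))
  x <- -half:half
  grid_r <- matrix(x, length(x), length(x))
  grid_c <- t(grid_r)
  lapply(seq_len(n_orient), function(k) {
    th <- (k - 1) * pi / n_orient
    u <- grid_c * cos(th) + grid_r * sin(th)   # across the bar
    v <- -grid_c * sin(th) + grid_r * cos(th)  # along the bar
    supp <- abs(v) <= len / 2 & abs(u) <= 3 * sigma
    ker <- matrix(0, length(x), length(x))
    ker[supp] <- -exp(-u[supp]^2 / (2 * sigma^2))
    ker[supp] <- ker[supp] - mean(ker[supp])
    ker / sqrt(sum(ker^2))  # unit energy: responses comparable across scales
  })
}

#' Z-profile of oriented matched-filter responses
#'
#' Classic vessel matched filtering: at each scale a bank of rotated
#' zero-mean Gaussian-profile kernels is correlated with the image and the
#' maximal response over orientations retained, then summarized across
#' scales.
#'
#' @param img preprocessed intensity matrix.
#' @param scale_set scale set.
#' @param n_orient number of kernel orientations over 180 degrees.
#' @return a [zprofile()].
#' @export
matched_filter_zprofile <- function(img, scale_set, n_orient = 12L) {
  zprofile(matched_responses(img, scale_set, n_orient)$resp, "matched")
}

# shared engine for the matched filter and the confidence measure: per
# scale, the orientation-maximal raw response and the orientation-maximal
# normalized correlation (local contrast removed)
matched_responses <- function(img, scale_set, n_orient = 12L) {
  pad <- rep(ceiling(1.5 * max(scale_set$scales)) + 2L, 2L)
  ctx <- conv_ctx(img, pad)
  resp <- vector("list", length(scale_set$scales))
  ncc <- resp
  for (s in seq_along(scale_set$scales)) {
    lam <- scale_set$scales[s]
    kers <- matched_filter_kernels(lam, n_orient)
    nsupp <- prod(dim(kers[[1]]))
    hks <- (dim(kers[[1]])[1] - 1L) %/% 2L
    mu <- box_mean(img, hks)
    ex2 <- box_mean(img^2, hks)
    sd_loc <- sqrt(pmax(ex2 - mu^2, 0))
    best <- best_ncc <- matrix(-Inf, nrow(img), ncol(img))
    for (ker in kers) {
      ri <- ctx_conv(ctx, ker)
      best <- pmax(best, ri)
      nc <- ri / (pmax(sd_loc, 1e-9) * sqrt(sum(ker^2)) * sqrt(nsupp))
      nc[sd_loc < 1e-9] <- 0
      best_ncc <- pmax(best_ncc, nc)
    }
    resp[[s]] <- best
    ncc[[s]] <- best_ncc
  }
  list(resp = resp, ncc = ncc)
}

#' Z-profile of the Gaussian-smoothed gradient magnitude
#'
#' At each scale the image is differentiated with Gaussian-derivative
#' kernels at sigma `l / 2` and the gradient magnitude taken; the stack is
#' then summarized across scales.
#'
#' @inheritParams frangi_zprofile
#' @return a [zprofile()].
#' @export
gradient_magnitude_zprofile <- function(img, scale_set) {
  ctx <- conv_ctx(img, hessian_pad(scale_set))
  resp <- lapply(scale_set$scales, function(lam) {
    sigma <- lam / 2
    gx <- ff2(img, gaussian_deriv_kernel(sigma, c(0L, 1L)), ctx)
    gy <- ff2(img, gaussian_deriv_kernel(sigma, c(1L, 0L)), ctx)
    sqrt(gx^2 + gy^2)
  })
  zprofile(resp, "gradient")
}

#' Vessel confidence measure
#'
#' A contrast-invariant agreement score between the local intensity
#' configuration and an ideal vessel cross-section: the normalized
#' correlation between the image (locally centred and scaled over the kernel
#' support) and the oriented matched-filter profile, maximized over
#' orientations and scales and clipped to \[0, 1\]. Flat regions, where the
#' local standard deviation vanishes, score zero.
#'
#' @inheritParams frangi_zprofile
#' @param n_orient number of profile orientations.
#' @param responses optional precomputed bank shared with the matched
#'   filter (internal reuse); computed when `NULL`.
#' @return a single matrix in \[0, 1\].
#' @export
vessel_confidence <- function(img, scale_set, n_orient = 12L,
                              responses = NULL) {
  if (is.null(responses))
    responses <- matched_responses(img, scale_set, n_orient)
  conf <- Reduce(pmax, responses$ncc)
  pmin(pmax(conf, 0), 1)
}

#' Z-profile of granulometric residues of the enhanced image
#'
#' Granular decomposition by openings of increasing size: the residue at
#' scale `l_k` is `opening(I, SE_{k-1}) - opening(I, SE_k)` (with the
#' identity for the zeroth opening), isolating bright structures whose size
#' lies between consecutive scales. Applied to the top/bottom-hat enhanced
#' image, whose bright granules delineate the non-vessel surround.
#'
#' @param enhanced an `enhanced_image` from [top_bottom_hat_enhance()], or a
#'   plain matrix.
#' @param scale_set scale set.
#' @return a [zprofile()] over the residue maps.
#' @export
granular_zprofile <- function(enhanced, scale_set) {
  img <- if (inherits(enhanced, "enhanced_image")) enhanced$pixels
         else enhanced
  prev <- img
  resp <- lapply(scale_set$scales, function(lam) {
    op <- EBImage::opening(img, disc_brush(lam))
    r <- prev - op
    prev <<- op
    r
  })
  zprofile(resp, "granular")
}

# real Gabor kernel with DC removed (envelope-weighted), unit aspect ratio
gabor_kernel <- function(wavelength, theta, sigma) {
  half <- ceiling(3 * sigma)
  x <- -half:half
  grid_r <- matrix(x, length(x), length(x))
  grid_c <- t(grid_r)
  u <- grid_c * cos(theta) + grid_r * sin(theta)
  env <- exp(-(grid_r^2 + grid_c^2) / (2 * sigma^2))
  k0 <- env * cos(2 * pi * u / wavelength)
  k0 - env * sum(k0) / sum(env)
}

#' Z-profile of oriented Gabor responses
#'
#' At each scale a bank of zero-DC real Gabor kernels (wavelength `2 * l`,
#' sigma `0.56 *` wavelength, unit aspect ratio) is applied and the maximal
#' response over orientations retained. Operates on the complement of the
#' enhanced image, where vessels appear bright.
#'
#' @param img_complement complement image (`1 - enhanced`).
#' @param scale_set scale set.
#' @param n_orient number of orientations over 180 degrees.
#' @return a [zprofile()].
#' @export
gabor_zprofile <- function(img_complement, scale_set, n_orient = 12L) {
  pad <- rep(ceiling(3 * 0.56 * 2 * max(scale_set$scales)) + 2L, 2L)
  ctx <- conv_ctx(img_complement, pad)
  resp <- lapply(scale_set$scales, function(lam) {
    wl <- 2 * lam
    sigma <- 0.56 * wl
    r <- NULL
    for (k in seq_len(n_orient)) {
      ker <- gabor_kernel(wl, (k - 1) * pi / n_orient, sigma)
      ri <- ctx_conv(ctx, ker)
      r <- if (is.null(r)) ri else pmax(r, ri)
    }
    r
  })
  zprofile(resp, "gabor")
}

zp_maps <- function(zp) {
  list(z_max = zp$z_max, z_mean = zp$z_mean,
       z_var = zp$z_var, z_interq = zp$z_interq)
}

#' Assemble the per-pixel feature stack
#'
#' Concatenates the filter-based features in a fixed, documented order --
#' the differentiable domain (Frangi, matched filter, gradient magnitude
#' Z-profiles: 4 each, plus the 1-map vessel confidence = 13), the spatial
#' domain (granulometry Z-profile: 4), the Gabor domain (4) -- and, when
#' supplied, 16 deep activation maps, for 21 or 37 named maps.
#'
#' @param frangi,matched,gradient,granular,gabor [zprofile()] objects.
#' @param confidence single confidence matrix.
#' @param deep_maps optional list of 16 equal-shape matrices.
#' @return object of class `feature_stack` with `maps` (named list),
#'   `names`, and a `standardization` slot (`NULL` until fitted).
#' @export
assemble_stack <- function(frangi, matched, gradient, confidence,
                           granular, gabor, deep_maps = NULL) {
  maps <- c(stats::setNames(zp_maps(frangi),
                            paste0("frangi.", names(zp_maps(frangi)))),
            stats::setNames(zp_maps(matched),
                            paste0("matched.", names(zp_maps(matched)))),
            stats::setNames(zp_maps(gradient),
                            paste0("gradient.", names(zp_maps(gradient)))),
            list(confidence = confidence),
            stats::setNames(zp_maps(granular),
                            paste0("granular.", names(zp_maps(granular)))),
            stats::setNames(zp_maps(gabor),
                            paste0("gabor.", names(zp_maps(gabor)))))
  if (!is.null(deep_maps)) {
    if (length(deep_maps) != 16L)
      stop("deep_maps must contain exactly 16 maps")
    maps <- c(maps, stats::setNames(deep_maps,
                                    sprintf("deep.%02d", 1:16)))
  }
  shp <- dim(maps[[1]])
  ok <- vapply(maps, function(m) identical(dim(m), shp), logical(1))
  if (!all(ok)) stop("shape mismatch among feature maps")
  structure(list(maps = maps, names = names(maps), standardization = NULL),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("Feature stack:", length(x$maps), "maps of",
      paste(dim(x$maps[[1]]), collapse = " x "),
      if (is.null(x$standardization)) "(raw)" else "(standardized)", "\n")
  invisible(x)
}

#' Flatten a feature stack to a pixel-by-feature matrix
#'
#' @param stack a `feature_stack`.
#' @param keep optional logical matrix selecting pixels (e.g. a border mask).
#' @return numeric matrix with one column per feature map.
#' @export
feature_matrix <- function(stack, keep = NULL) {
  m <- vapply(stack$maps,
              function(mp) if (is.null(keep)) as.vector(mp) else mp[keep],
              numeric(if (is.null(keep)) length(stack$maps[[1]])
                      else sum(keep)))
  colnames(m) <- stack$names
  m
}

#' Standardize a feature stack
#'
#' Each map is centred and scaled. In fit mode (`params = NULL`) the mean
#' and standard deviation are estimated from this stack and recorded; in
#' transform mode the supplied training-set parameters are applied
#' unchanged, so test images never contribute to the statistics.
#'
#' @param stack a `feature_stack`.
#' @param params optional named list of `(mean, sd)` pairs saved from a
#'   previous fit (the stack's `standardization` slot).
#' @return the stack with standardized maps and `standardization` filled.
#' @export
standardize <- function(stack, params = NULL) {
  stopifnot(inherits(stack, "feature_stack"))
  fit <- is.null(params)
  if (fit)
    params <- lapply(stack$maps, function(m) {
      s <- stats::sd(m)
      list(mean = mean(m), sd = s)
    })
  if (!identical(names(params), stack$names))
    stop("standardization parameters do not match the feature manifest")
  for (nm in stack$names) {
    p <- params[[nm]]
    if (!is.finite(p$sd) || p$sd <= 0) {
      warning("zero-variance feature map '", nm, "' standardized to zeros")
      stack$maps[[nm]] <- stack$maps[[nm]] * 0
    } else {
      stack$maps[[nm]] <- (stack$maps[[nm]] - p$mean) / p$sd
    }
  }
  stack$standardization <- params
  stack
}

#' Fit column standardization parameters on a pixel matrix
#'
#' @param x numeric matrix (pixels x features).
#' @return named list of `(mean, sd)` per column.
#' @export
fit_standardization <- function(x) {
  stats::setNames(lapply(seq_len(ncol(x)), function(j)
    list(mean = mean(x[, j]), sd = stats::sd(x[, j]))),
    colnames(x))
}

#' Apply saved standardization parameters to a pixel matrix
#'
#' @param x numeric matrix whose columns match `params` by name.
#' @param params output of [fit_standardization()] (or a stack's
#'   `standardization` slot).
#' @return standardized matrix.
#' @export
apply_standardization <- function(x, params) {
  if (!identical(colnames(x), names(params)))
    stop("feature columns do not match the standardization manifest")
  for (j in seq_len(ncol(x))) {
    p <- params[[j]]
    x[, j] <- if (!is.finite(p$sd) || p$sd <= 0) 0
              else (x[, j] - p$mean) / p$sd
  }
  x
}
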