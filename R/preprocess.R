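#' Detect the imaging window and exclude border regions
#'
#' Clinical angiography frames carry a collimator border of near-constant
#' intensity outside the imaging window. Without DICOM metadata the border is
#' recovered from the image itself: pixels whose intensity sits within `tol`
#' of the modal corner intensity, connected to the frame edge, form the
#' border; everything else is the imaging window. If the candidate region
#' covers less than half of the outer pixel ring the frame is taken to be
#' borderless and an all-true mask is returned.
#'
#' @param x an `angiogram` (its stored `border_mask` is returned as-is) or a
#'   numeric intensity matrix in \[0, 1\].
#' @param tol intensity tolerance for the constant-border test.
#' @return logical matrix, `TRUE` inside the imaging window.
#' @export
exclude_border <- function(x, tol = 0.02) {
  if (inherits(x, "angiogram")) {
    if (!is.null(x$border_mask)) return(x$border_mask)
    x <- x$pixels
  }
  stopifnot(is.matrix(x))
  d <- dim(x)
  corners <- c(x[1, 1], x[1, d[2]], x[d[1], 1], x[d[1], d[2]])
  ref <- stats::median(corners)
  cand <- abs(x - ref) <= tol
  ring <- row(x) == 1 | row(x) == d[1] | col(x) == 1 | col(x) == d[2]
  if (sum(cand & ring) < 0.5 * sum(ring))
    return(matrix(TRUE, d[1], d[2]))
  lab <- EBImage::bwlabel(cand)
  edge_labels <- setdiff(unique(c(lab[ring])), 0)
  border <- matrix(lab %in% edge_labels, d[1], d[2])
  !border
}

# replicate-padded shift of a matrix by (dr, dc)
shift_pad <- function(x, dr, dc) {
  d <- dim(x)
  ri <- pmin(pmax(seq_len(d[1]) + dr, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2]) + dc, 1L), d[2])
  x[ri, ci, drop = FALSE]
}

#' Estimate the Gaussian noise level of an image
#'
#' Immerkaer's fast estimator: the absolute response of a Laplacian-difference
#' kernel, averaged over the image, is proportional to the noise standard
#' deviation and nearly blind to image structure.
#'
#' @param img numeric matrix.
#' @return estimated noise standard deviation.
#' @export
estimate_noise_sd <- function(img) {
  k <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  r <- EBImage::filter2(img, k, boundary = "replicate")
  d <- dim(img)
  sqrt(pi / 2) / (6 * (d[1] - 2) * (d[2] - 2)) *
    sum(abs(r[2:(d[1] - 1), 2:(d[2] - 1)]))
}

#' Non-local means denoising
#'
#' Patch-based averaging: every pixel is replaced by a weighted mean of
#' pixels within a search window, weighted by the similarity of their
#' surrounding patches. Implemented with the offset decomposition (one
#' box-filtered squared-difference image per search offset), which makes the
#' cost linear in image size times search-window area.
#'
#' @param img numeric matrix, intensities in \[0, 1\].
#' @param patch odd patch width for the similarity measure (default 5).
#' @param search odd search-window width (default 11).
#' @param h filtering strength; defaults to `0.8 *` the estimated noise sd.
#' @param sigma noise sd; estimated with [estimate_noise_sd()] when `NULL`.
#' @return denoised matrix of the same shape.
#' @export
denoise_nlm <- function(img, patch = 5L, search = 11L, h = NULL,
                        sigma = NULL) {
  stopifnot(is.matrix(img), patch %% 2 == 1, search %% 2 == 1)
  if (is.null(sigma)) sigma <- estimate_noise_sd(img)
  if (is.null(h)) h <- max(0.8 * sigma, 1e-6)
  half <- (search - 1L) %/% 2L
  acc <- img  # self offset, weight exp(0) = 1
  wsum <- matrix(1, nrow(img), ncol(img))
  for (dr in -half:half) {
    for (dc in -half:half) {
      if (dr == 0 && dc == 0) next
      sh <- shift_pad(img, dr, dc)
      d2 <- box_mean((img - sh)^2, (patch - 1L) %/% 2L)
      w <- exp(-pmax(d2 - 2 * sigma^2, 0) / h^2)
      acc <- acc + w * sh
      wsum <- wsum + w
    }
  }
  acc / wsum
}

# mean over a (2h+1)^2 box with replicate boundary, via integral images
box_mean <- function(x, h) {
  d <- dim(x)
  ri <- pmin(pmax(seq_len(d[1] + 2L * h) - h, 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2] + 2L * h) - h, 1L), d[2])
  p <- x[ri, ci]
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  s <- rbind(0, cbind(0, t(s)))
  w <- 2L * h + 1L
  (s[w + seq_len(d[1]), w + seq_len(d[2])] -
     s[seq_len(d[1]), w + seq_len(d[2])] -
     s[w + seq_len(d[1]), seq_len(d[2])] +
     s[seq_len(d[1]), seq_len(d[2])]) / w^2
}

#' Build the logarithmic scale set anchored to the catheter diameter
#'
#' Filter scales are tied to the physical calibre of coronary arteries:
#' `n_scales` values log-spaced from `0.66 * cath_px` to `6.33 * cath_px`
#' inclusive, so consecutive scales share a constant ratio.
#'
#' @param cath_px catheter diameter in pixels (> 0).
#' @param n_scales number of scales (>= 2), default 10.
#' @return object of class `scale_set` with fields `scales`, `cath_px`,
#'   `n_scales`.
#' @export
build_scale_set <- function(cath_px, n_scales = 10L) {
  if (!is.numeric(cath_px) || cath_px <= 0)
    stop("cath_px must be positive")
  stopifnot(n_scales >= 2)
  scales <- cath_px * exp(seq(log(0.66), log(6.33),
                              length.out = n_scales))
  structure(list(scales = scales, cath_px = cath_px,
                 n_scales = as.integer(n_scales)),
            class = "scale_set")
}

# flat disc structuring element of diameter lambda (odd size >= 3)
disc_brush <- function(lambda) {
  size <- max(3L, 2L * floor(lambda / 2) + 1L)
  EBImage::makeBrush(size, shape = "disc")
}

#' Multi-scale top/bottom-hat contrast enhancement
#'
#' Computes the maximal top-hat residue `I_top = max_l (I - opening(I, SE_l))`
#' and bottom-hat residue `I_bottom = max_l (closing(I, SE_l) - I)` over the
#' scale set (disc structuring elements of diameter `l`), and returns
#' `I + m * I_top - n * I_bottom` clipped to \[0, 1\]. With dark vessels the
#' bottom-hat term deepens vessels while the top-hat term brightens the
#' background, stretching the vessel/background contrast.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param scale_set a [build_scale_set()] result.
#' @param m,n nonnegative strengths of the top-hat and bottom-hat terms.
#' @return object of class `enhanced_image`: `pixels` (clipped result),
#'   `i_top`, `i_bottom`, `m`, `n`, `scale_set`.
#' @export
top_bottom_hat_enhance <- function(img, scale_set, m = 1, n = 1) {
  stopifnot(inherits(scale_set, "scale_set"), m >= 0, n >= 0)
  if (length(scale_set$scales) == 0) stop("empty scale set")
  i_top <- matrix(0, nrow(img), ncol(img))
  i_bottom <- i_top
  for (lam in scale_set$scales) {
    se <- disc_brush(lam)
    i_top <- pmax(i_top, img - EBImage::opening(img, se))
    i_bottom <- pmax(i_bottom, EBImage::closing(img, se) - img)
  }
  out <- pmin(pmax(img + m * i_top - n * i_bottom, 0), 1)
  structure(list(pixels = out, i_top = i_top, i_bottom = i_bottom,
                 m = m, n = n, scale_set = scale_set),
            class = "enhanced_image")
}

# Correlation filtering with replicate boundary. Direct calls go through a
# per-image FFT cache: the replicate-padded image is transformed once and
# every kernel costs one forward and one inverse FFT on an FFT-friendly
# grid, which is much cheaper than re-padding per call and also lifts the
# kernel-not-larger-than-image restriction.
conv_ctx <- function(img, pad = NULL) {
  d <- dim(img)
  if (is.null(pad)) pad <- d %/% 2L
  pad <- pmax(pad, 2L)
  P <- c(stats::nextn(d[1] + 2L * pad[1], c(2, 3)),
         stats::nextn(d[2] + 2L * pad[2], c(2, 3)))
  ri <- pmin(pmax(seq_len(d[1] + 2L * pad[1]) - pad[1], 1L), d[1])
  ci <- pmin(pmax(seq_len(d[2] + 2L * pad[2]) - pad[2], 1L), d[2])
  big <- matrix(0, P[1], P[2])
  big[seq_along(ri), seq_along(ci)] <- img[ri, ci]
  structure(list(fi = stats::fft(big), d = d, pad = pad, P = P),
            class = "conv_ctx")
}

ctx_conv <- function(ctx, ker) {
  kd <- dim(ker)
  kh <- (kd - 1L) %/% 2L
  if (any(kh >= ctx$pad))
    stop("kernel exceeds the convolution context padding")
  K <- matrix(0, ctx$P[1], ctx$P[2])
  # kernel wrapped around the origin (orientation matches EBImage::filter2)
  rr <- ((-kh[1]:kh[1]) %% ctx$P[1]) + 1L
  cc <- ((-kh[2]:kh[2]) %% ctx$P[2]) + 1L
  K[rr, cc] <- ker
  out <- Re(stats::fft(ctx$fi * stats::fft(K), inverse = TRUE)) /
    prod(ctx$P)
  out[ctx$pad[1] + seq_len(ctx$d[1]), ctx$pad[2] + seq_len(ctx$d[2])]
}

ff2 <- function(img, ker, ctx = NULL) {
  if (inherits(img, "conv_ctx")) return(ctx_conv(img, ker))
  if (!is.null(ctx)) return(ctx_conv(ctx, ker))
  ctx_conv(conv_ctx(img, pad = (dim(ker) - 1L) %/% 2L + 1L), ker)
}

# separable Gaussian-derivative kernel; deriv = c(order_row, order_col)
gaussian_deriv_kernel <- function(sigma, deriv = c(0L, 0L)) {
  half <- max(1L, ceiling(3 * sigma))
  x <- -half:half
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  d1 <- -x / sigma^2 * g
  d2 <- (x^2 / sigma^2 - 1) / sigma^2 * g
  pick <- function(o) switch(o + 1L, g, d1, d2)
  outer(pick(deriv[1]), pick(deriv[2]))
}

# scale-normalized Hessian (gamma = 2) of img at Gaussian sigma
hessian_at_scale <- function(img, sigma, ctx = NULL) {
  s2 <- sigma^2
  list(xx = s2 * ff2(img, gaussian_deriv_kernel(sigma, c(2L, 0L)), ctx),
       xy = s2 * ff2(img, gaussian_deriv_kernel(sigma, c(1L, 1L)), ctx),
       yy = s2 * ff2(img, gaussian_deriv_kernel(sigma, c(0L, 2L)), ctx))
}

# eigen decomposition of a field of symmetric 2x2 matrices;
# returns eigenvalues ordered by |l1| <= |l2| and the unit eigenvector of l2
hessian_eigen <- function(h) {
  tr <- h$xx + h$yy
  disc <- sqrt(pmax(((h$xx - h$yy) / 2)^2 + h$xy^2, 0))
  la <- tr / 2 + disc
  lb <- tr / 2 - disc
  swap <- abs(la) < abs(lb)
  l2 <- ifelse(swap, lb, la)
  l1 <- ifelse(swap, la, lb)
  # eigenvector for eigenvalue l2: (xy, l2 - xx), degenerate -> (1, 0)
  vx <- h$xy
  vy <- l2 - h$xx
  nrm <- sqrt(vx^2 + vy^2)
  deg <- nrm < 1e-12
  vx <- ifelse(deg, 1, vx / pmax(nrm, 1e-12))
  vy <- ifelse(deg, 0, vy / pmax(nrm, 1e-12))
  list(l1 = l1, l2 = l2, v2x = vx, v2y = vy)
}

#' Vesselness-enhancing anisotropic diffusion
#'
#' Iteratively smooths the image along locally tubular structures while
#' suppressing diffusion across them. Each iteration computes the Hessian at
#' the given sigma, derives a dark-ridge vesselness response, and diffuses
#' with a tensor whose conductivity is 1 along the vessel direction (the
#' eigenvector of the small-magnitude eigenvalue) and
#' `eps + (1 - eps) * (1 - v)` across it, using an explicit scheme.
#'
#' @param img numeric matrix.
#' @param scale_set scale set; the diffusion sigma defaults to half the
#'   geometric mean scale.
#' @param iterations number of explicit steps (0 returns the input).
#' @param dt time step of the explicit scheme (stability requires <= 0.25).
#' @param eps residual cross-vessel conductivity in (0, 1).
#' @return diffused matrix of the same shape.
#' @export
vesselness_diffusion <- function(img, scale_set, iterations = 5L, dt = 0.15,
                                 eps = 0.05) {
  stopifnot(inherits(scale_set, "scale_set"), iterations >= 0)
  if (iterations == 0) return(img)
  sigma <- exp(mean(log(scale_set$scales))) / 2
  dx <- function(z) (shift_pad(z, 0L, 1L) - shift_pad(z, 0L, -1L)) / 2
  dy <- function(z) (shift_pad(z, 1L, 0L) - shift_pad(z, -1L, 0L)) / 2
  out <- img
  for (it in seq_len(iterations)) {
    h <- hessian_at_scale(out, sigma)
    e <- hessian_eigen(h)
    v <- frangi_response(e, beta = 0.5)
    # tensor D = R diag(1, c_across) R^T with R = [v1 | v2]; v1 is the
    # along-vessel direction, orthogonal to (v2x, v2y)
    c_across <- eps + (1 - eps) * (1 - v)
    a <- e$v2y^2 + c_across * e$v2x^2       # D[1,1] (row direction = y)
    b <- (c_across - 1) * e$v2x * e$v2y     # D[1,2]
    cc <- e$v2x^2 + c_across * e$v2y^2      # D[2,2]
    gy <- dy(out); gx <- dx(out)
    j1 <- a * gy + b * gx
    j2 <- b * gy + cc * gx
    out <- out + dt * (dy(j1) + dx(j2))
  }
  out
}
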