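#' Configuration for the synthetic angiogram generator
#'
#' Bundles the knobs that control one synthetic X-ray coronary angiography
#' (XCA) frame: canvas size, the catheter reference diameter `cath_px` that
#' anchors all physical scales, the size of the simulated vascular tree, the
#' vessel area the frame should carry, the additive noise level, and which
#' confounding structures (catheter shadow, spine-like bands, illumination
#' gradient) are painted in.
#'
#' Defaults emulate clinical frames: 512x512 canvas, catheter diameter 8 px,
#' and a vessel fraction around 5.6% of the frame.
#'
#' @param seed integer seed controlling all randomness of the frame.
#' @param canvas integer vector (height, width) in pixels, both >= 64.
#' @param cath_px catheter diameter in pixels (> 0); the length reference.
#' @param n_branches number of side branches grafted onto the root vessel.
#' @param vessel_fraction_target target fraction of annotated vessel pixels,
#'   in (0, 0.2].
#' @param noise_sigma standard deviation of additive Gaussian intensity noise
#'   (intensities live in \[0, 1\]).
#' @param confounders named list of logical flags `catheter`, `spine_bands`,
#'   `illumination_gradient`.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         canvas = c(512L, 512L),
                         cath_px = 8,
                         n_branches = 7L,
                         vessel_fraction_target = 0.056,
                         noise_sigma = 0.03,
                         confounders = list(catheter = TRUE,
                                            spine_bands = TRUE,
                                            illumination_gradient = TRUE)) {
  stopifnot(length(canvas) == 2, all(canvas >= 64))
  if (!is.numeric(cath_px) || cath_px <= 0)
    stop("cath_px must be a positive number")
  if (vessel_fraction_target <= 0 || vessel_fraction_target > 0.2)
    stop("vessel_fraction_target must lie in (0, 0.2]")
  if (n_branches < 0) stop("n_branches must be >= 0")
  flags <- list(catheter = TRUE, spine_bands = TRUE,
                illumination_gradient = TRUE)
  flags[names(confounders)] <- lapply(confounders, isTRUE)
  structure(list(seed = as.integer(seed),
                 canvas = as.integer(canvas),
                 cath_px = cath_px,
                 n_branches = as.integer(n_branches),
                 vessel_fraction_target = vessel_fraction_target,
                 noise_sigma = noise_sigma,
                 confounders = flags),
            class = "synth_config")
}

# random walk for one centerline; heading is reflected away from a margin so
# segments stay inside the canvas and the tree's area budget is predictable
walk_centerline <- function(start, heading, length, canvas, step = 2,
                            wiggle = 0.12, margin = 12) {
  n <- max(2L, ceiling(length / step))
  pts <- matrix(NA_real_, n, 2)
  pos <- start
  ctr <- canvas / 2
  for (i in seq_len(n)) {
    pts[i, ] <- pos
    heading <- heading + stats::rnorm(1, 0, wiggle)
    nxt <- pos + step * c(sin(heading), cos(heading))
    if (any(nxt < margin) || any(nxt > canvas - margin)) {
      # steer back toward the canvas centre instead of leaving the frame
      heading <- atan2(ctr[1] - pos[1], ctr[2] - pos[2]) +
        stats::rnorm(1, 0, 0.3)
      nxt <- pos + step * c(sin(heading), cos(heading))
    }
    pos <- pmin(pmax(nxt, margin), canvas - margin)
  }
  pts
}

#' Generate a synthetic coronary tree
#'
#' Grows a connected tree of polyline segments rooted at one frame edge.
#' Segment diameters taper strictly from parent to child and are rescaled so
#' that the annotated-vessel area (segments with diameter >= 0.75 x `cath_px`)
#' matches `vessel_fraction_target` of the canvas. Diameters are kept within
#' \[0.3, 2.0\] x `cath_px`, so the smallest twigs fall below the annotation
#' threshold on purpose: they are rendered but never enter the ground-truth
#' mask, as in clinical annotation protocols.
#'
#' @param config a [synth_config()].
#' @return list with `segments` (each a list of `points` (n x 2, row/col),
#'   `diameter`, `parent` index) and `cath_px`.
#' @export
generate_vessel_tree <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  canvas <- config$canvas
  if (any(canvas < 64)) stop("canvas too small to place the root segment")
  set.seed(config$seed)
  cath <- config$cath_px

  edge <- sample(4, 1)  # 1 top, 2 bottom, 3 left, 4 right
  along <- stats::runif(1, 0.25, 0.75)
  start <- switch(edge,
                  c(13, along * canvas[2]),
                  c(canvas[1] - 13, along * canvas[2]),
                  c(along * canvas[1], 13),
                  c(along * canvas[1], canvas[2] - 13))
  heading <- switch(edge, pi / 2 * 0, pi, pi / 2, -pi / 2)
  # headings measured so that (sin h, cos h) points inward
  heading <- switch(edge,
                    stats::runif(1, 0.25 * pi, 0.75 * pi),
                    stats::runif(1, -0.75 * pi, -0.25 * pi),
                    stats::runif(1, -0.25 * pi, 0.25 * pi),
                    stats::runif(1, 0.75 * pi, 1.25 * pi))
  root_len <- 0.85 * min(canvas)
  segments <- list(list(points = walk_centerline(start, heading, root_len,
                                                 canvas),
                        diameter = 1.7 * cath, parent = 0L))

  for (b in seq_len(config$n_branches)) {
    parent <- sample(length(segments), 1)
    ppts <- segments[[parent]]$points
    at <- sample(seq(2, nrow(ppts) - 1), 1)
    pdiam <- segments[[parent]]$diameter
    ratio <- stats::runif(1, 0.5, 0.85)
    diam <- max(pdiam * ratio, 0.3 * cath)
    diam <- min(diam, 0.95 * pdiam)  # strictly smaller than parent
    dvec <- ppts[min(at + 1, nrow(ppts)), ] - ppts[at - 1, ]
    phead <- atan2(dvec[1], dvec[2])
    turn <- sample(c(-1, 1), 1) * stats::runif(1, 0.35, 1.0)
    len <- stats::runif(1, 0.25, 0.55) * 0.85 * min(canvas)
    segments[[length(segments) + 1L]] <-
      list(points = walk_centerline(ppts[at, ], phead + turn, len, canvas),
           diameter = diam, parent = parent)
  }

  # rescale diameters so the annotated area hits the target fraction;
  # the 1.10 factor compensates junction overlap and soft-profile loss
  target_area <- config$vessel_fraction_target * prod(canvas)
  seg_len <- vapply(segments, function(s)
    sum(sqrt(rowSums(diff(s$points)^2))), numeric(1))
  for (pass in 1:3) {
    diam <- vapply(segments, `[[`, numeric(1), "diameter")
    annotated <- diam >= 0.75 * cath
    est <- sum(seg_len[annotated] * diam[annotated])
    if (est <= 0) break
    sc <- 1.10 * target_area / est
    # never scale the trunk below the annotation threshold: a frame with an
    # empty ground-truth mask is useless downstream
    sc <- max(sc, 0.85 * cath / max(diam))
    for (i in seq_along(segments))
      segments[[i]]$diameter <-
        min(max(segments[[i]]$diameter * sc, 0.3 * cath), 2.0 * cath)
  }
  list(segments = segments, cath_px = cath, canvas = canvas)
}

# stamp one tube into depth/radius buffers using max-combination
rasterize_segment <- function(depth, mask, pts, radius, dep, annotate,
                              step = 0.75) {
  dims <- dim(depth)
  # resample polyline at fixed arc step
  dl <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(dl))
  if (cum[length(cum)] < step) return(list(depth = depth, mask = mask))
  s <- seq(0, cum[length(cum)], by = step)
  ri <- stats::approx(cum, pts[, 1], xout = s)$y
  ci <- stats::approx(cum, pts[, 2], xout = s)$y
  w <- ceiling(2.2 * radius)
  sigma <- radius / 1.18  # FWHM equals the vessel diameter
  for (k in seq_along(s)) {
    r0 <- max(1L, floor(ri[k]) - w); r1 <- min(dims[1], floor(ri[k]) + w)
    c0 <- max(1L, floor(ci[k]) - w); c1 <- min(dims[2], floor(ci[k]) + w)
    if (r0 > r1 || c0 > c1) next
    dr <- (r0:r1) - ri[k]; dc <- (c0:c1) - ci[k]
    d2 <- outer(dr^2, dc^2, "+")
    depth[r0:r1, c0:c1] <- pmax(depth[r0:r1, c0:c1],
                                dep * exp(-d2 / (2 * sigma^2)))
    if (annotate)
      mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | (d2 <= radius^2)
  }
  list(depth = depth, mask = mask)
}

#' Render a synthetic angiogram and its ground-truth mask
#'
#' Paints the tree as dark tubes with an inverted-Gaussian cross-section
#' (vessels attenuate X-rays, so they appear darker than the background) on a
#' bright background, adds the configured confounders and Gaussian noise, and
#' builds the annotation mask: exactly the pixels within half a diameter of a
#' centerline, for segments whose diameter is at least 0.75 x `cath_px`.
#'
#' @param tree output of [generate_vessel_tree()].
#' @param config the [synth_config()] used to build the tree.
#' @return list with `angiogram` (class `angiogram`: `pixels`, `cath_px`,
#'   `border_mask`, `view_label`) and `mask` (class `vessel_mask`: `labels`,
#'   `min_annotated_diameter`).
#' @export
render_angiogram <- function(tree, config) {
  stopifnot(inherits(config, "synth_config"))
  canvas <- config$canvas
  set.seed(config$seed + 1L)
  cath <- config$cath_px

  paint <- function(segs) {
    depth <- matrix(0, canvas[1], canvas[2])
    mask <- matrix(FALSE, canvas[1], canvas[2])
    for (seg in segs) {
      r <- seg$diameter / 2
      dep <- 0.20 + 0.10 * min(seg$diameter / cath, 2) / 2
      out <- rasterize_segment(depth, mask, seg$points, r, dep,
                               annotate = seg$diameter >= 0.75 * cath)
      depth <- out$depth; mask <- out$mask
    }
    list(depth = depth, mask = mask)
  }
  segs <- tree$segments
  px <- paint(segs)
  # junction overlap and boundary clipping shrink the realized area below
  # the tree's length x diameter estimate; correct with re-rasterization
  for (pass in 1:3) {
    f <- mean(px$mask)
    if (f <= 0 || abs(f - config$vessel_fraction_target) < 0.004) break
    sc <- config$vessel_fraction_target / f
    sc <- max(sc, 0.85 * cath / max(vapply(segs, `[[`, numeric(1),
                                           "diameter")))
    for (i in seq_along(segs))
      segs[[i]]$diameter <- min(max(segs[[i]]$diameter * sc, 0.3 * cath),
                                2.2 * cath)
    px <- paint(segs)
  }
  depth <- px$depth; mask <- px$mask

  bg <- matrix(0.78, canvas[1], canvas[2])
  rows <- row(bg); cols <- col(bg)
  if (config$confounders$illumination_gradient) {
    ang <- stats::runif(1, 0, 2 * pi)
    ramp <- (sin(ang) * (rows / canvas[1] - 0.5) +
             cos(ang) * (cols / canvas[2] - 0.5))
    bg <- bg + 0.08 * ramp
  }
  if (config$confounders$spine_bands) {
    nb <- sample(2:3, 1)
    for (i in seq_len(nb)) {
      ctr <- stats::runif(1, 0.15, 0.85) * canvas[2]
      wid <- stats::runif(1, 50, 90) * canvas[2] / 512
      amp <- stats::runif(1, 0.03, 0.06) * sample(c(-1, 1), 1)
      bg <- bg + amp * exp(-(cols - ctr)^2 / (2 * wid^2))
    }
  }
  if (config$confounders$catheter) {
    # straight low-contrast tube entering from the top edge
    x0 <- stats::runif(1, 0.1, 0.9) * canvas[2]
    slope <- stats::runif(1, -0.2, 0.2)
    pts <- cbind(seq(1, canvas[1], by = 2),
                 x0 + slope * seq(1, canvas[1], by = 2))
    pts[, 2] <- pmin(pmax(pts[, 2], 3), canvas[2] - 2)
    out <- rasterize_segment(depth, mask, pts, cath / 2, 0.10,
                             annotate = FALSE)
    depth <- out$depth
  }

  pixels <- bg - depth
  if (config$noise_sigma > 0)
    pixels <- pixels + matrix(stats::rnorm(prod(canvas), 0,
                                           config$noise_sigma),
                              canvas[1], canvas[2])
  # rectangular imaging window with a dark collimator frame
  inset <- 6L
  border_mask <- rows > inset & rows <= canvas[1] - inset &
    cols > inset & cols <= canvas[2] - inset
  pixels[!border_mask] <- 0.05
  pixels <- pmin(pmax(pixels, 0), 1)
  mask[!border_mask] <- FALSE

  ang <- structure(list(pixels = pixels, cath_px = cath,
                        border_mask = border_mask,
                        view_label = "LCA"),
                   class = "angiogram")
  msk <- structure(list(labels = mask,
                        min_annotated_diameter = 0.75 * cath),
                   class = "vessel_mask")
  list(angiogram = ang, mask = msk)
}

#' Generate a dataset of synthetic angiogram/mask pairs
#'
#' Per-image catheter diameters are drawn from a positive-truncated
#' Normal(8.0, 1.2) (the clinical catheter statistics), and each frame is
#' labelled a left (LCA) or right (RCA) coronary view with probability
#' `lca_fraction`. Fully deterministic under `seed`.
#'
#' @param n_images number of pairs (>= 1).
#' @param seed integer master seed.
#' @param lca_fraction probability of the LCA view label.
#' @param config template [synth_config()]; its seed/cath_px are overridden
#'   per image.
#' @return list of `n_images` elements, each a list(`angiogram`, `mask`).
#' @export
generate_dataset <- function(n_images, seed = 1L, lca_fraction = 80 / 130,
                             config = synth_config()) {
  stopifnot(n_images >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  caths <- numeric(n_images)
  for (i in seq_len(n_images)) {
    repeat {
      caths[i] <- stats::rnorm(1, 8.0, 1.2)
      if (caths[i] > 0) break
    }
  }
  views <- ifelse(stats::runif(n_images) < lca_fraction, "LCA", "RCA")
  lapply(seq_len(n_images), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$cath_px <- caths[i]
    tree <- generate_vessel_tree(cfg)
    pair <- render_angiogram(tree, cfg)
    pair$angiogram$view_label <- views[i]
    pair
  })
}

#' Write an angiogram/mask pair as PNG files with a JSON sidecar
#'
#' @param pair a list(`angiogram`, `mask`) from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @param id basename stem for the three files.
#' @return invisibly, the paths written.
#' @export
write_synth_pair <- function(pair, dir, id) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".png"))
  msk_path <- file.path(dir, paste0(id, "_mask.png"))
  meta_path <- file.path(dir, paste0(id, ".json"))
  png::writePNG(pair$angiogram$pixels, img_path)
  png::writePNG(pair$mask$labels * 1.0, msk_path)
  jsonlite::write_json(list(cath_px = pair$angiogram$cath_px,
                            view_label = pair$angiogram$view_label),
                       meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(img_path, msk_path, meta_path))
}

#' Read an angiogram/mask pair written by [write_synth_pair()]
#'
#' @param dir directory containing the files.
#' @param id basename stem.
#' @return list(`angiogram`, `mask`).
#' @export
read_synth_pair <- function(dir, id) {
  px <- png::readPNG(file.path(dir, paste0(id, ".png")))
  mk <- png::readPNG(file.path(dir, paste0(id, "_mask.png"))) > 0.5
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")))
  border <- exclude_border(px)
  list(angiogram = structure(list(pixels = px, cath_px = meta$cath_px,
                                  border_mask = border,
                                  view_label = meta$view_label),
                             class = "angiogram"),
       mask = structure(list(labels = mk,
                             min_annotated_diameter = 0.75 * meta$cath_px),
                        class = "vessel_mask"))
}
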