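#' Construct a pixel dataset
#'
#' Rows of (feature vector, binary label) with optional provenance (image
#' id, row, column) for pixels that still correspond to a physical location;
#' cluster-centroid rows are synthesized and carry no origin.
#'
#' @param features numeric matrix (N x D) with column names.
#' @param labels binary vector of length N.
#' @param origin optional data.frame with columns `image_id`, `row`, `col`.
#' @param stage name of the last sampling stage applied.
#' @return object of class `pixel_dataset`.
#' @export
pixel_dataset <- function(features, labels, origin = NULL, stage = "raw") {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            all(labels %in% c(0, 1)))
  if (!is.null(origin)) {
    stopifnot(nrow(origin) == nrow(features))
    key <- paste(origin$image_id, origin$row, origin$col)
    if (anyDuplicated(key)) stop("duplicate pixel origins")
  }
  structure(list(features = features, labels = as.integer(labels),
                 origin = origin, stage = stage),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("Pixel dataset [%s]: %d rows, %d features, %.3f%% positive\n",
              x$stage, nrow(x$features), ncol(x$features),
              100 * mean(x$labels)))
  invisible(x)
}

subset_dataset <- function(ds, keep, stage = ds$stage) {
  pixel_dataset(ds$features[keep, , drop = FALSE], ds$labels[keep],
                if (is.null(ds$origin)) NULL
                else ds$origin[keep, , drop = FALSE],
                stage)
}

#' Extract all in-border pixels of one image as a dataset
#'
#' @param stack a `feature_stack` for the image.
#' @param mask a `vessel_mask` or logical matrix of vessel labels.
#' @param border_mask logical matrix, `TRUE` inside the imaging window.
#' @param image_id identifier recorded in the origin columns.
#' @return a `pixel_dataset` with stage `"raw"`.
#' @export
extract_pixels <- function(stack, mask, border_mask, image_id = "img") {
  labels <- if (inherits(mask, "vessel_mask")) mask$labels else mask
  keep <- border_mask
  feats <- feature_matrix(stack, keep)
  idx <- which(keep, arr.ind = TRUE)
  pixel_dataset(feats, as.integer(labels[keep]),
                data.frame(image_id = image_id, row = idx[, 1],
                           col = idx[, 2]),
                stage = "raw")
}

# deterministic lattice offset for an image id
offset_for_id <- function(image_id) {
  h <- sum(utf8ToInt(as.character(image_id)))
  c(h %% 2L, (h %/% 2L) %% 2L)
}

#' Uniform under-sampling of background pixels
#'
#' Thins the majority (background) class on a stride-2 lattice so that the
#' 8-neighborhood of every retained pixel contains no other retained pixel.
#' Positive pixels are never touched; only in-border negatives are
#' considered. The lattice offset is deterministic per image.
#'
#' @param negative_mask logical matrix, `TRUE` at background pixels.
#' @param border_mask logical matrix of the imaging window.
#' @param offset integer vector (row, col) in `{0, 1}^2`; lattice phase.
#' @return integer matrix of retained (row, col) coordinates.
#' @export
uniform_undersample <- function(negative_mask, border_mask,
                                offset = c(0L, 0L)) {
  stopifnot(identical(dim(negative_mask), dim(border_mask)))
  d <- dim(negative_mask)
  lattice <- (row(negative_mask) - 1L - offset[1]) %% 2L == 0L &
    (col(negative_mask) - 1L - offset[2]) %% 2L == 0L
  which(negative_mask & border_mask & lattice, arr.ind = TRUE)
}

#' Intensity-based unsupervised under-sampling
#'
#' Removes background candidates that are unambiguously background by
#' intensity alone. A 256-bin histogram of the enhanced image (in-border
#' pixels) is smoothed with a 1-D median filter; the bin where the raw pdf
#' most exceeds the smoothed pdf marks the over-saturation peak created by
#' contrast enhancement. Excluding that peak's pixels, the median of the
#' remaining intensities is the binarization threshold: retained negatives
#' brighter than it are dropped, and the image-wide bright mask is kept as
#' the "unsupervised background mask" for post-processing.
#'
#' @param enhanced an `enhanced_image` (or plain matrix in \[0, 1\]).
#' @param neg_coords integer (row, col) matrix of candidate negatives,
#'   e.g. from [uniform_undersample()].
#' @param border_mask logical matrix of the imaging window.
#' @param bins histogram resolution (default 256).
#' @param medfilt_width odd median-filter width in bins (default 5).
#' @return list with `kept` (coordinate matrix), `removal_mask` (logical,
#'   bright in-border pixels), `threshold`, `peak_bin`.
#' @export
unsupervised_undersample <- function(enhanced, neg_coords, border_mask,
                                     bins = 256L, medfilt_width = 5L) {
  img <- if (inherits(enhanced, "enhanced_image")) enhanced$pixels
         else enhanced
  vals <- img[border_mask]
  if (diff(range(vals)) < 1e-12) {
    warning("degenerate single-intensity image; keeping all negatives")
    return(list(kept = neg_coords,
                removal_mask = matrix(FALSE, nrow(img), ncol(img)),
                threshold = Inf, peak_bin = NA_integer_))
  }
  bin_of <- function(v) pmin(pmax(floor(v * bins) + 1L, 1L), bins)
  counts <- tabulate(bin_of(vals), nbins = bins)
  pdf <- counts / sum(counts)
  smoothed <- stats::runmed(pdf, medfilt_width)
  peak <- which.max(pdf - smoothed)
  rest <- vals[bin_of(vals) != peak]
  threshold <- stats::median(rest)
  removal_mask <- img > threshold & border_mask
  keep <- img[neg_coords] <= threshold
  list(kept = neg_coords[keep, , drop = FALSE],
       removal_mask = removal_mask, threshold = threshold,
       peak_bin = peak)
}

# nearest-neighbour indices under Euclidean distance, chunked so the full
# N x N distance matrix is never materialized
nearest_neighbor_index <- function(x, chunk = 2048L) {
  n <- nrow(x)
  sq <- rowSums(x^2)
  nn <- integer(n)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE],
                                                   x)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[idx] <- max.col(-d2, ties.method = "first")
  }
  nn
}

#' Tomek-link removal
#'
#' A Tomek link is a pair of mutually nearest neighbours with opposite
#' labels; both members sit on the class boundary and removing them (from
#' both classes) sharpens it. Links are removed repeatedly until a scan of
#' the remaining points finds none, so the output is link-free and a second
#' call is the identity.
#'
#' @param ds a `pixel_dataset` with standardized features.
#' @param iterate repeat until no links remain (default `TRUE`); `FALSE`
#'   performs the classic single pass over the input links.
#' @return the filtered `pixel_dataset` (stage `"tomek"`).
#' @export
tomek_links <- function(ds, iterate = TRUE) {
  stopifnot(inherits(ds, "pixel_dataset"))
  if (length(unique(ds$labels)) < 2) {
    warning("single-class dataset; Tomek-link removal is the identity")
    ds$stage <- "tomek"
    return(ds)
  }
  x <- ds$features
  n <- nrow(x)
  keep <- rep(TRUE, n)
  nn <- nearest_neighbor_index(x)
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    mutual <- act[act < nn[act] & keep[nn[act]] & nn[nn[act]] == act &
                    ds$labels[act] != ds$labels[nn[act]]]
    if (!length(mutual)) break
    keep[c(mutual, nn[mutual])] <- FALSE
    if (!iterate) break
    # only points whose nearest neighbour vanished need a new one
    stale <- which(keep & !keep[nn])
    if (!length(stale)) break
    surv <- which(keep)
    sq <- rowSums(x[surv, , drop = FALSE]^2)
    for (start in seq(1, length(stale), by = 2048L)) {
      idx <- stale[start:min(start + 2047L, length(stale))]
      d2 <- outer(rowSums(x[idx, , drop = FALSE]^2), sq, "+") -
        2 * tcrossprod(x[idx, , drop = FALSE], x[surv, , drop = FALSE])
      d2[cbind(seq_along(idx), match(idx, surv))] <- Inf
      nn[idx] <- surv[max.col(-d2, ties.method = "first")]
    }
  }
  subset_dataset(ds, keep, stage = "tomek")
}

#' Cluster-centroid under-sampling
#'
#' Replaces each class by `per_class_target` k-means centroids of its
#' feature vectors, producing an exactly balanced dataset of synthesized
#' rows (no pixel origins). If a class holds fewer points than the target,
#' all of its points are kept unchanged, with a warning.
#'
#' @param ds a `pixel_dataset` with standardized features.
#' @param per_class_target desired points per class (e.g. 4000).
#' @param iter_max k-means iteration cap (Lloyd's algorithm).
#' @param seed optional seed for the k-means initialization.
#' @return a `pixel_dataset` (stage `"cluster_centroid"`).
#' @export
cluster_centroid <- function(ds, per_class_target, iter_max = 10L,
                             seed = NULL) {
  stopifnot(inherits(ds, "pixel_dataset"), per_class_target >= 1)
  if (!is.null(seed)) set.seed(seed)
  reduce <- function(cls) {
    x <- ds$features[ds$labels == cls, , drop = FALSE]
    if (nrow(x) < per_class_target) {
      warning("class ", cls, " has fewer points (", nrow(x),
              ") than the target; keeping all")
      return(x)
    }
    if (nrow(x) == per_class_target) return(x)
    km <- suppressWarnings(stats::kmeans(x, centers = per_class_target,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd"))
    ctr <- km$centers
    colnames(ctr) <- colnames(x)
    ctr
  }
  neg <- reduce(0L)
  pos <- reduce(1L)
  pixel_dataset(rbind(neg, pos),
                c(rep(0L, nrow(neg)), rep(1L, nrow(pos))),
                origin = NULL, stage = "cluster_centroid")
}

#' Pool per-image pixel datasets
#'
#' @param ds_list list of `pixel_dataset` objects with identical feature
#'   manifests.
#' @param stage stage label of the pooled dataset.
#' @return one `pixel_dataset`.
#' @export
pool_datasets <- function(ds_list, stage = ds_list[[1]]$stage) {
  feats <- do.call(rbind, lapply(ds_list, `[[`, "features"))
  labels <- unlist(lapply(ds_list, `[[`, "labels"))
  origins <- lapply(ds_list, `[[`, "origin")
  origin <- if (any(vapply(origins, is.null, logical(1)))) NULL
            else do.call(rbind, origins)
  pixel_dataset(feats, labels, origin, stage)
}

#' Run the under-sampling cascade for one image
#'
#' Applies, in order: uniform lattice thinning of negatives, intensity-based
#' removal of bright negatives, Tomek-link removal, and cluster-centroid
#' reduction. Positives pass the first two stages untouched. Any suffix of
#' stages can be disabled; each stage's output dataset is retained for
#' auditing via [build_report()].
#'
#' @param ds the image's raw `pixel_dataset` from [extract_pixels()].
#' @param enhanced the image's `enhanced_image` (for the intensity stage).
#' @param border_mask logical matrix of the imaging window.
#' @param stages character vector among
#'   `c("uniform", "unsupervised", "tomek", "centroid")`.
#' @param per_class centroid target per class (default 4000).
#' @param centroid_iter_max k-means iteration cap for the centroid stage.
#' @param image_id image identifier (sets the lattice offset).
#' @return list with `dataset` (final), `stages` (named list of per-stage
#'   datasets including `"raw"`), and `removal_mask` (unsupervised
#'   background mask, or `NULL`).
#' @export
run_sampling_cascade <- function(ds, enhanced, border_mask,
                                 stages = c("uniform", "unsupervised",
                                            "tomek", "centroid"),
                                 per_class = 4000L,
                                 centroid_iter_max = 10L,
                                 image_id = "img") {
  out <- list(raw = ds)
  cur <- ds
  removal_mask <- NULL
  coord_key <- function(d) paste(d$origin$row, d$origin$col)
  if ("uniform" %in% stages) {
    neg_mask <- matrix(FALSE, nrow(border_mask), ncol(border_mask))
    neg_mask[as.matrix(cur$origin[cur$labels == 0, c("row", "col")])] <- TRUE
    kept <- uniform_undersample(neg_mask, border_mask,
                                offset_for_id(image_id))
    sel <- cur$labels == 1 |
      coord_key(cur) %in% paste(kept[, 1], kept[, 2])
    cur <- subset_dataset(cur, sel, stage = "uniform")
    out$uniform <- cur
  }
  if ("unsupervised" %in% stages) {
    negc <- as.matrix(cur$origin[cur$labels == 0, c("row", "col")])
    res <- unsupervised_undersample(enhanced, negc, border_mask)
    removal_mask <- res$removal_mask
    sel <- cur$labels == 1 |
      coord_key(cur) %in% paste(res$kept[, 1], res$kept[, 2])
    cur <- subset_dataset(cur, sel, stage = "unsupervised")
    out$unsupervised <- cur
  }
  if ("tomek" %in% stages) {
    cur <- tomek_links(cur)
    out$tomek <- cur
  }
  if ("centroid" %in% stages) {
    cur <- cluster_centroid(cur, per_class,
                            iter_max = centroid_iter_max)
    out$centroid <- cur
  }
  list(dataset = cur, stages = out, removal_mask = removal_mask)
}

#' Per-stage audit report of the sampling cascade
#'
#' @param stage_datasets named list of `pixel_dataset` objects in cascade
#'   order (e.g. the `stages` element of [run_sampling_cascade()]), or a
#'   list of such lists from several images, which are then pooled
#'   stage-wise.
#' @return object of class `sampler_report`: a data.frame with columns
#'   `stage`, `positive_pct`, `negative_pct`, `total`.
#' @export
build_report <- function(stage_datasets) {
  if (inherits(stage_datasets[[1]], "pixel_dataset")) {
    counts <- lapply(stage_datasets, function(d)
      c(pos = sum(d$labels == 1), total = length(d$labels)))
  } else {
    stage_names <- names(stage_datasets[[1]])
    counts <- lapply(stats::setNames(stage_names, stage_names),
                     function(nm) {
      per <- vapply(stage_datasets, function(img)
        c(sum(img[[nm]]$labels == 1), length(img[[nm]]$labels)),
        numeric(2))
      c(pos = sum(per[1, ]), total = sum(per[2, ]))
    })
  }
  df <- data.frame(stage = names(counts),
                   positive_pct = unname(vapply(counts, function(x)
                     100 * x[["pos"]] / x[["total"]], numeric(1))),
                   negative_pct = unname(vapply(counts, function(x)
                     100 * (1 - x[["pos"]] / x[["total"]]), numeric(1))),
                   total = unname(vapply(counts, `[[`, numeric(1),
                                         "total")),
                   row.names = NULL)
  structure(df, class = c("sampler_report", "data.frame"))
}

#' @export
print.sampler_report <- function(x, ...) {
  y <- x
  y$positive_pct <- sprintf("%.3f", y$positive_pct)
  y$negative_pct <- sprintf("%.3f", y$negative_pct)
  print.data.frame(y)
  invisible(x)
}
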