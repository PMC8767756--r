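#' Otsu binarization of a probability map
#'
#' Exhaustive search over the discretized threshold range for the value
#' maximizing the between-class variance of the probability histogram; ties
#' break toward the lower threshold. Pixels strictly above the threshold
#' become foreground.
#'
#' @param prob numeric matrix in \[0, 1\].
#' @param levels histogram resolution (default 256).
#' @return list with `mask` (logical matrix) and `threshold`.
#' @export
binarize_otsu <- function(prob, levels = 256L) {
  stopifnot(all(prob >= 0 & prob <= 1))
  if (diff(range(prob)) < 1e-12) {
    warning("constant probability map; returning all-background mask")
    return(list(mask = matrix(FALSE, nrow(prob), ncol(prob)),
                threshold = NA_real_))
  }
  bin <- pmin(pmax(floor(prob * levels) + 1L, 1L), levels)
  counts <- tabulate(bin, nbins = levels)
  p <- counts / sum(counts)
  mids <- (seq_len(levels) - 0.5) / levels
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  # between-class variance for threshold after bin k
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  k <- which.max(bcv)  # which.max returns the first (lowest) maximizer
  threshold <- k / levels
  list(mask = prob > threshold, threshold = threshold)
}

# 8-connected component labelling via union of pixel adjacencies
label_components_8 <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(list(labels = integer(0), idx = idx))
  pos <- match(seq_len(prod(d)), idx)  # pixel index -> node id
  edges <- integer(0)
  rr <- ((idx - 1L) %% d[1]) + 1L
  cc <- ((idx - 1L) %/% d[1]) + 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rr + off[1]; nc <- cc + off[2]
    ok <- nr >= 1L & nr <= d[1] & nc >= 1L & nc <= d[2]
    nidx <- (nc - 1L) * d[1] + nr
    ok[ok] <- mask[nidx[ok]]
    if (any(ok))
      edges <- c(edges, rbind(pos[idx[ok]], pos[nidx[ok]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  list(labels = igraph::components(g)$membership, idx = idx)
}

#' Post-process a binary segmentation mask
#'
#' Applies the three clean-up rules in order: border pixels are forced to
#' background, pixels of the unsupervised background mask (certain
#' background by intensity) are forced to background, and 8-connected
#' components with area below `min_area` pixels are removed as artifacts.
#'
#' @param mask logical prediction matrix.
#' @param border_mask logical imaging-window matrix.
#' @param background_mask optional logical matrix of certain-background
#'   pixels (the `removal_mask` of [unsupervised_undersample()]).
#' @param min_area components strictly smaller than this survive removal
#'   threshold (default 50 px).
#' @return cleaned logical matrix.
#' @export
postprocess_mask <- function(mask, border_mask, background_mask = NULL,
                             min_area = 50L) {
  stopifnot(identical(dim(mask), dim(border_mask)))
  out <- mask & border_mask
  if (!is.null(background_mask)) out <- out & !background_mask
  lab <- label_components_8(out)
  if (length(lab$idx)) {
    sizes <- tabulate(lab$labels)
    small <- sizes[lab$labels] < min_area
    out[lab$idx[small]] <- FALSE
  }
  out
}

#' Segmentation metrics from prediction and truth masks
#'
#' Precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' F1 = 2*precision*sensitivity/(precision+sensitivity), and
#' IoU = TP/(TP+FP+FN), computed over in-border pixels only. A metric with
#' a zero denominator is reported as `NA` (undefined), never silently 0.
#'
#' @param pred logical prediction matrix.
#' @param truth logical (or `vessel_mask`) ground truth.
#' @param border_mask logical imaging-window matrix.
#' @return named list: the five metrics plus the TP/FP/FN/TN counts.
#' @export
seg_metrics <- function(pred, truth, border_mask) {
  if (inherits(truth, "vessel_mask")) truth <- truth$labels
  stopifnot(identical(dim(pred), dim(truth)))
  p <- pred[border_mask]; t <- truth[border_mask]
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  list(precision = precision, sensitivity = sensitivity,
       specificity = safe(tn, tn + fp), f1 = f1,
       iou = safe(tp, tp + fp + fn),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Area under the ROC curve
#'
#' Computed as the Wilcoxon rank statistic: the probability that a randomly
#' chosen vessel pixel outscores a randomly chosen background pixel, with
#' ties credited one half.
#'
#' @param scores numeric scores (e.g. a probability map); matrices are
#'   subset by `border_mask` when given.
#' @param labels binary labels aligned with `scores`.
#' @param border_mask optional logical matrix applied to both arguments.
#' @return AUROC in \[0, 1\], or `NA` when one class is absent.
#' @export
auroc <- function(scores, labels, border_mask = NULL) {
  if (!is.null(border_mask)) {
    scores <- scores[border_mask]
    labels <- labels[border_mask]
  }
  labels <- as.integer(labels > 0)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("single-class truth; AUROC undefined")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Permutation feature importance
#'
#' For each feature, its column is shuffled `repeats` times on held-out
#' pixels and the model's mean squared error (probability versus label) is
#' recomputed each time; the importance is the mean increase in MSE over
#' the unpermuted baseline -- equivalently the decrease of the squared-error
#' criterion caused by destroying that feature.
#'
#' @param model a `vessel_model`.
#' @param x held-out feature matrix (standardized as in training).
#' @param y binary labels.
#' @param repeats permutations per feature (default 10).
#' @param seed integer seed; identical seeds give identical reports.
#' @return object of class `importance_report`: data.frame with `feature`,
#'   `importance` (mean criterion decrease), `sd` over repeats.
#' @export
permutation_importance <- function(model, x, y, repeats = 10L, seed = 1L) {
  stopifnot(repeats >= 1)
  set.seed(seed)
  base_mse <- mean((predict(model, x) - y)^2)
  res <- lapply(seq_len(ncol(x)), function(j) {
    dec <- vapply(seq_len(repeats), function(r) {
      xp <- x
      xp[, j] <- xp[sample.int(nrow(x)), j]
      mean((predict(model, xp) - y)^2) - base_mse
    }, numeric(1))
    c(mean = mean(dec), sd = stats::sd(dec))
  })
  df <- data.frame(feature = colnames(x),
                   importance = vapply(res, `[[`, numeric(1), "mean"),
                   sd = vapply(res, `[[`, numeric(1), "sd"),
                   row.names = NULL)
  structure(df, class = c("importance_report", "data.frame"),
            repeats = as.integer(repeats), base_mse = base_mse)
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Permutation importance (", attr(x, "repeats"),
      " repeats, baseline MSE ", sprintf("%.5f", attr(x, "base_mse")),
      ")\n", sep = "")
  print.data.frame(x[order(-x$importance), ], row.names = FALSE)
  invisible(x)
}
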