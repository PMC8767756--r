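#' Z-profile: summary statistics of a filter response across scales
#'
#' Reduces a stack of per-scale response maps to four per-pixel statistics:
#' maximum, mean, population variance, and interquartile range (Q3 - Q1,
#' linear interpolation between order statistics). These summarize how a
#' pixel's filter response evolves over the scale set without committing to
#' a single best scale.
#'
#' @param responses either a 3-D array (height x width x n_scales) or a list
#'   of equal-shape matrices, one per scale; at least 2 scales.
#' @param source_filter optional name of the filter that produced the stack.
#' @return object of class `zprofile` with matrices `z_max`, `z_mean`,
#'   `z_var`, `z_interq` and the `source_filter` name.
#' @export
zprofile <- function(responses, source_filter = "filter") {
  if (is.list(responses))
    responses <- array(unlist(responses, use.names = FALSE),
                       dim = c(dim(responses[[1]]), length(responses)))
  stopifnot(length(dim(responses)) == 3)
  d <- dim(responses)
  s <- d[3]
  if (s < 2) stop("Z-profile needs at least 2 scales")
  m <- matrix(responses, ncol = s)
  z_mean <- rowMeans(m)
  z_var <- rowMeans(m^2) - z_mean^2
  z_var <- pmax(z_var, 0)
  srt <- row_sort(m)
  z_max <- srt[, s]
  q1 <- row_quantile_sorted(srt, 0.25)
  q3 <- row_quantile_sorted(srt, 0.75)
  shape <- function(v) matrix(v, d[1], d[2])
  structure(list(z_max = shape(z_max), z_mean = shape(z_mean),
                 z_var = shape(z_var), z_interq = shape(q3 - q1),
                 source_filter = source_filter),
            class = "zprofile")
}

# sort each row of a matrix; selection-sort over columns, efficient when the
# number of columns (scales) is small
row_sort <- function(m) {
  s <- ncol(m)
  out <- m
  work <- m
  big <- max(m) + 1
  for (k in seq_len(s)) {
    idx <- max.col(-work, ties.method = "first")
    mn <- work[cbind(seq_len(nrow(m)), idx)]
    out[, k] <- mn
    work[cbind(seq_len(nrow(m)), idx)] <- big
  }
  out
}

# quantile (type 7, linear interpolation) from row-sorted data
row_quantile_sorted <- function(srt, p) {
  s <- ncol(srt)
  h <- (s - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  srt[, lo] + (h - lo) * (srt[, hi] - srt[, lo])
}

#' @export
print.zprofile <- function(x, ...) {
  cat("Z-profile of", x$source_filter, "responses:",
      paste(dim(x$z_max), collapse = " x "), "pixels\n")
  cat(sprintf("  z_max range [%.4g, %.4g], z_mean range [%.4g, %.4g]\n",
              min(x$z_max), max(x$z_max), min(x$z_mean), max(x$z_mean)))
  invisible(x)
}
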