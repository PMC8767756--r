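#' Preprocess an angiogram and extract its feature stack
#'
#' Runs the full per-image front end: border detection, non-local-means
#' denoising, top/bottom-hat contrast enhancement over the catheter-anchored
#' scale set, vesselness-enhancing diffusion, then the filter feature bank
#' (Frangi, matched filter, gradient magnitude, vessel confidence on the
#' diffused image; granulometry on the enhanced image; Gabor on its
#' complement) and, when a checkpoint is given, the 16 deep activation maps.
#' The returned stack is unstandardized.
#'
#' @param angiogram an `angiogram` or plain intensity matrix.
#' @param cath_px catheter diameter; taken from the angiogram when present,
#'   else defaults to 8 (the population mean).
#' @param n_scales number of log-spaced scales (default 10).
#' @param m,n top-hat / bottom-hat strengths.
#' @param diffusion_iters vesselness-diffusion iterations (default 5).
#' @param denoise run non-local means first (default `TRUE`).
#' @param checkpoint optional `unet_checkpoint` for the 16 deep maps.
#' @param n_orient orientations for the matched/Gabor banks.
#' @return list: `stack` (`feature_stack`), `enhanced` (`enhanced_image`),
#'   `border_mask`, `preprocessed` (diffused image), `scale_set`.
#' @export
extract_features <- function(angiogram, cath_px = NULL, n_scales = 10L,
                             m = 1, n = 1, diffusion_iters = 5L,
                             denoise = TRUE, checkpoint = NULL,
                             n_orient = 12L) {
  if (inherits(angiogram, "angiogram")) {
    img <- angiogram$pixels
    border <- exclude_border(angiogram)
    if (is.null(cath_px)) cath_px <- angiogram$cath_px
  } else {
    img <- angiogram
    border <- exclude_border(img)
  }
  if (is.null(cath_px)) cath_px <- 8
  scale_set <- build_scale_set(cath_px, n_scales)
  work <- if (denoise) denoise_nlm(img) else img
  enhanced <- top_bottom_hat_enhance(work, scale_set, m = m, n = n)
  diffused <- vesselness_diffusion(work, scale_set,
                                   iterations = diffusion_iters)
  deep_maps <- if (!is.null(checkpoint))
    extract_deep_features(checkpoint, img)
  stack <- assemble_stack(
    frangi = frangi_zprofile(diffused, scale_set),
    matched = matched_filter_zprofile(diffused, scale_set, n_orient),
    gradient = gradient_magnitude_zprofile(diffused, scale_set),
    confidence = vessel_confidence(diffused, scale_set, n_orient),
    granular = granular_zprofile(enhanced, scale_set),
    gabor = gabor_zprofile(1 - enhanced$pixels, scale_set, n_orient),
    deep_maps = deep_maps)
  list(stack = stack, enhanced = enhanced, border_mask = border,
       preprocessed = diffused, scale_set = scale_set)
}

#' Train the full segmentation pipeline on angiogram/mask pairs
#'
#' For each training image: features are extracted, the raw pixel dataset
#' built, and the under-sampling cascade run (the supervised stages operate
#' on standardized features, with standardization fitted once on the pooled
#' raw training pixels). The per-image datasets are pooled and the chosen
#' classifier fitted. Optionally tunes the GBDT grid first.
#'
#' @param pairs list of `list(angiogram, mask)` training pairs.
#' @param method `"gbdt"` or `"deep_forest"`.
#' @param stages sampling cascade stages (see [run_sampling_cascade()]).
#' @param per_class cluster-centroid target per class.
#' @param config GBDT configuration list, or `NULL` for defaults.
#' @param tune_grid optional grid for [tune_gbdt()]; when given, tuning
#'   runs before the final fit and overrides `config`.
#' @param checkpoint optional deep-feature checkpoint (37-feature mode).
#' @param seed integer seed.
#' @param ... passed on to [extract_features()].
#' @return object of class `vessel_pipeline`: the fitted `model`, the
#'   `sampler_report`, the feature/standardization manifests, and the
#'   extraction settings needed to segment new images.
#' @export
train_pipeline <- function(pairs, method = "gbdt",
                           stages = c("uniform", "unsupervised"),
                           per_class = 4000L, config = NULL,
                           tune_grid = NULL, checkpoint = NULL,
                           seed = 1L, ...) {
  stopifnot(length(pairs) >= 1)
  extraction <- list(...)
  feats <- vector("list", length(pairs))
  raw <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    fx <- extract_features(pairs[[i]]$angiogram, checkpoint = checkpoint,
                           ...)
    raw[[i]] <- extract_pixels(fx$stack, pairs[[i]]$mask, fx$border_mask,
                               image_id = paste0("img", i))
    feats[[i]] <- fx
  }
  std <- fit_standardization(pool_datasets(raw)$features)
  cascades <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    ds <- raw[[i]]
    ds$features <- apply_standardization(ds$features, std)
    cascades[[i]] <- run_sampling_cascade(
      ds, feats[[i]]$enhanced, feats[[i]]$border_mask,
      stages = stages, per_class = per_class,
      image_id = paste0("img", i))
  }
  report <- build_report(lapply(cascades, `[[`, "stages"))
  if (!is.null(tune_grid) && method == "gbdt") {
    ds_by_img <- stats::setNames(raw, paste0("img", seq_along(raw)))
    config <- tune_gbdt(ds_by_img, grid = tune_grid, seed = seed)$config
  }
  pooled <- pool_datasets(lapply(cascades, `[[`, "dataset"))
  model <- fit_vessel_model(pooled$features, pooled$labels,
                            method = method, config = config,
                            standardization = std, seed = seed)
  structure(list(model = model, report = report,
                 standardization = std, stages = stages,
                 per_class = per_class, checkpoint = checkpoint,
                 extraction = extraction),
            class = "vessel_pipeline")
}

#' @export
print.vessel_pipeline <- function(x, ...) {
  cat("Trained vessel segmentation pipeline\n")
  print(x$model)
  cat("Sampling cascade:", paste(x$stages, collapse = " -> "), "\n")
  print(x$report)
  invisible(x)
}

#' Segment a new angiogram with a trained pipeline
#'
#' Extracts features with the training-time settings, standardizes them
#' with the saved training parameters, predicts the per-pixel probability
#' map, binarizes it with Otsu's method, and post-processes (border
#' removal, unsupervised background mask, small-artifact removal). When
#' ground truth is supplied, the six evaluation metrics are attached.
#'
#' @param pipeline a `vessel_pipeline` from [train_pipeline()].
#' @param angiogram the frame to segment.
#' @param truth optional `vessel_mask` for evaluation.
#' @param min_area artifact-removal area threshold (default 50 px).
#' @return object of class `segmentation_result`: `prob` (probability
#'   map), `mask` (final binary mask), `threshold`, `metrics` (or `NULL`),
#'   `border_mask`.
#' @export
segment_image <- function(pipeline, angiogram, truth = NULL,
                          min_area = 50L) {
  fx <- do.call(extract_features,
                c(list(angiogram, checkpoint = pipeline$checkpoint),
                  pipeline$extraction))
  prob <- predict(pipeline$model, fx$stack, fx$border_mask)
  bin <- binarize_otsu(prob)
  bg_mask <- if ("unsupervised" %in% pipeline$stages) {
    neg0 <- matrix(FALSE, nrow(prob), ncol(prob))
    unsupervised_undersample(fx$enhanced,
                             which(neg0, arr.ind = TRUE),
                             fx$border_mask)$removal_mask
  }
  mask <- postprocess_mask(bin$mask, fx$border_mask, bg_mask,
                           min_area = min_area)
  metrics <- if (!is.null(truth)) {
    m <- seg_metrics(mask, truth, fx$border_mask)
    m$auroc <- auroc(prob, if (inherits(truth, "vessel_mask"))
      truth$labels else truth, fx$border_mask)
    m
  }
  structure(list(prob = prob, mask = mask, threshold = bin$threshold,
                 metrics = metrics, border_mask = fx$border_mask),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Segmentation result:", sum(x$mask), "vessel pixels, Otsu threshold",
      sprintf("%.3f", x$threshold), "\n")
  if (!is.null(x$metrics))
    cat(sprintf(paste0("  precision %.3f  sensitivity %.3f  specificity",
                       " %.3f\n  F1 %.3f  IoU %.3f  AUROC %.3f\n"),
                x$metrics$precision, x$metrics$sensitivity,
                x$metrics$specificity, x$metrics$f1, x$metrics$iou,
                x$metrics$auroc))
  invisible(x)
}

#' Single-feature baseline segmentation
#'
#' The reference a learned pixel classifier must beat: the Frangi `z_max`
#' map alone, Otsu-binarized and post-processed the same way.
#'
#' @param angiogram frame to segment.
#' @param truth optional ground truth for metrics.
#' @param ... passed to [extract_features()] (typically `n_scales`).
#' @return a `segmentation_result`.
#' @export
baseline_frangi_otsu <- function(angiogram, truth = NULL, ...) {
  fx <- extract_features(angiogram, ...)
  score <- fx$stack$maps[["frangi.z_max"]]
  score <- normalize_minmax(score)
  score[!fx$border_mask] <- 0
  bin <- binarize_otsu(score)
  mask <- postprocess_mask(bin$mask, fx$border_mask, min_area = 50L)
  metrics <- if (!is.null(truth)) {
    m <- seg_metrics(mask, truth, fx$border_mask)
    m$auroc <- auroc(score, if (inherits(truth, "vessel_mask"))
      truth$labels else truth, fx$border_mask)
    m
  }
  structure(list(prob = score, mask = mask, threshold = bin$threshold,
                 metrics = metrics, border_mask = fx$border_mask),
            class = "segmentation_result")
}
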