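#' Stratified image-level train/test split
#'
#' Images (never pixels) are assigned to sets, stratified by view label and
#' source so each set carries approximately the same LCA/RCA and source mix.
#' The deep-learning mode uses a 3:1:1 train/validation/test split; the
#' ensemble mode uses 4:1 and, by construction, reuses exactly the
#' deep-learning test images: its training set is the union of the deep
#' train and validation sets.
#'
#' @param meta data.frame with columns `id`, `view_label`, and optionally
#'   `source`.
#' @param mode `"ensemble"` (4:1) or `"deep"` (3:1:1).
#' @param seed integer seed; identical seeds give identical assignments.
#' @return object of class `split_plan`: data.frame with columns `id`,
#'   `view_label`, `source`, `set`.
#' @export
make_split <- function(meta, mode = c("ensemble", "deep"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(nrow(meta) >= 5, all(c("id", "view_label") %in% names(meta)))
  if (is.null(meta$source)) meta$source <- "default"
  set.seed(seed)
  meta$set <- NA_character_
  strata <- split(seq_len(nrow(meta)),
                  paste(meta$view_label, meta$source))
  small <- vapply(strata, length, integer(1)) < 5
  if (any(small)) {
    warning("strata smaller than the fold count merged")
    merged <- unlist(strata[small], use.names = FALSE)
    strata <- c(strata[!small], if (length(merged)) list(merged = merged))
  }
  for (idx in strata) {
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_test <- round(n / 5)
    n_val <- round(n / 5)
    test <- idx[seq_len(n_test)]
    val <- idx[n_test + seq_len(n_val)]
    train <- setdiff(idx, c(test, val))
    meta$set[test] <- "test"
    if (mode == "deep") {
      meta$set[val] <- "validation"
      meta$set[train] <- "train"
    } else {
      meta$set[c(val, train)] <- "train"
    }
  }
  structure(meta[, c("id", "view_label", "source", "set")],
            class = c("split_plan", "data.frame"))
}

default_gbdt_grid <- function() {
  expand.grid(learning_rate = c(0.01, 0.05, 0.1),
              n_stages = c(100L, 500L, 1000L, 2000L),
              max_depth = c(3L, 5L, 10L, 20L))
}

fit_gbdt_raw <- function(x, y, config, seed = 1L) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = list(objective = "binary:logistic",
                                   eta = config$learning_rate,
                                   max_depth = config$max_depth,
                                   nthread = 1,
                                   seed = seed),
                     data = dtrain, nrounds = config$n_stages,
                     verbose = 0)
}

predict_gbdt_raw <- function(model, x) {
  stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))
}

#' Tune GBDT hyper-parameters by image-level cross-validation
#'
#' Four-fold cross-validation with cyclic fold composition: the training
#' images are ordered (deterministically shuffled under `seed`), cut into
#' four contiguous blocks, and each fold validates on one block while
#' training on the other three (a 3:1 ratio). Standardization is re-fitted
#' on each fold's training pixels and applied to its validation pixels, so
#' no fold leaks statistics. The grid point with the highest mean pooled
#' validation AUROC wins (ties break toward the earlier grid row).
#'
#' @param datasets named list (by image id) of `pixel_dataset` objects with
#'   raw (unstandardized) features for the training images.
#' @param grid data.frame with columns `learning_rate`, `n_stages`,
#'   `max_depth`; defaults to the full 3 x 4 x 4 tuning grid.
#' @param folds number of cyclic folds (default 4).
#' @param seed integer seed.
#' @return list with `config` (winning row as a list), `cv` (grid with a
#'   `mean_auroc` column), and `n_fits`.
#' @export
tune_gbdt <- function(datasets, grid = default_gbdt_grid(), folds = 4L,
                      seed = 1L) {
  if (nrow(grid) == 0) stop("empty tuning grid")
  set.seed(seed)
  ids <- names(datasets)[sample.int(length(datasets))]
  blocks <- split(ids, cut(seq_along(ids), folds, labels = FALSE))
  n_fits <- 0L
  scores <- matrix(NA_real_, nrow(grid), folds)
  fold_data <- lapply(seq_len(folds), function(k) {
    val_ids <- blocks[[k]]
    tr <- pool_datasets(datasets[setdiff(ids, val_ids)])
    va <- pool_datasets(datasets[val_ids])
    std <- fit_standardization(tr$features)
    list(xtr = apply_standardization(tr$features, std), ytr = tr$labels,
         xva = apply_standardization(va$features, std), yva = va$labels)
  })
  for (g in seq_len(nrow(grid))) {
    for (k in seq_len(folds)) {
      fd <- fold_data[[k]]
      model <- fit_gbdt_raw(fd$xtr, fd$ytr, as.list(grid[g, ]),
                            seed = seed + k)
      p <- predict_gbdt_raw(model, fd$xva)
      scores[g, k] <- auroc(p, fd$yva)
      n_fits <- n_fits + 1L
    }
  }
  grid$mean_auroc <- rowMeans(scores)
  best <- which.max(grid$mean_auroc)
  list(config = as.list(grid[best, c("learning_rate", "n_stages",
                                     "max_depth")]),
       cv = grid, n_fits = n_fits)
}

#' Fit a per-pixel vessel classifier
#'
#' The model-fitting entry point of the package. `method = "gbdt"` trains
#' gradient-boosted trees with the given (or default) learning rate, number
#' of boosting stages and tree depth; `method = "deep_forest"` trains a
#' cascade forest (see [fit_deep_forest()]) with its default
#' hyper-parameters. The feature manifest and, when supplied, the
#' training-set standardization parameters travel with the model so
#' prediction can verify and reproduce them.
#'
#' @param x numeric feature matrix (rows = pixels) with column names, or a
#'   `pixel_dataset`.
#' @param y binary labels (ignored when `x` is a `pixel_dataset`).
#' @param method `"gbdt"` or `"deep_forest"`.
#' @param config for GBDT, a list with `learning_rate`, `n_stages`,
#'   `max_depth` (e.g. from [tune_gbdt()]); defaults to
#'   `list(learning_rate = 0.1, n_stages = 100, max_depth = 5)`.
#' @param standardization optional [fit_standardization()] parameters
#'   recorded for later use on test stacks.
#' @param seed integer seed.
#' @return object of class `c("vessel_<method>", "vessel_model")`.
#' @export
fit_vessel_model <- function(x, y = NULL,
                             method = c("gbdt", "deep_forest"),
                             config = NULL, standardization = NULL,
                             seed = 1L) {
  method <- match.arg(method)
  if (inherits(x, "pixel_dataset")) {
    y <- x$labels
    x <- x$features
  }
  stopifnot(is.matrix(x), length(y) == nrow(x))
  if (length(unique(y)) < 2) stop("single-class training input")
  if (method == "gbdt") {
    if (is.null(config))
      config <- list(learning_rate = 0.1, n_stages = 100L, max_depth = 5L)
    fitted <- fit_gbdt_raw(x, y, config, seed)
    cls <- "vessel_gbdt"
  } else {
    fitted <- fit_deep_forest_raw(x, y, seed = seed)
    config <- fitted$config
    cls <- "vessel_deep_forest"
  }
  structure(list(kind = method, fitted = fitted, config = config,
                 feature_names = colnames(x),
                 standardization = standardization, seed = seed),
            class = c(cls, "vessel_model"))
}

#' Fit a cascade ("deep") forest classifier
#'
#' Layered ensemble: every layer holds two random forests and two
#' completely-random forests (extra-trees with a single random split
#' variable). Layer k consumes the original features concatenated with the
#' previous layer's eight class-probability columns; depth grows while the
#' layer's internally cross-validated accuracy improves, up to a cap. All
#' hyper-parameters are defaults -- cascade forests are deliberately run
#' untuned.
#'
#' @param x feature matrix or `pixel_dataset`.
#' @param y binary labels.
#' @param seed integer seed.
#' @return a `vessel_model` of kind `deep_forest`.
#' @export
fit_deep_forest <- function(x, y = NULL, seed = 1L) {
  fit_vessel_model(x, y, method = "deep_forest", seed = seed)
}

# cascade-forest internals: each layer holds 2 random forests and 2
# completely-random (extra-trees, mtry 1) forests; layer k consumes the
# original features plus the previous layer's 8 class-probability columns
cascade_layer_fit <- function(x, y, trees, seed) {
  df <- data.frame(x, y = factor(y, levels = c(0, 1)))
  lapply(seq_len(4L), function(j) {
    ranger::ranger(y ~ ., data = df, num.trees = trees,
                   probability = TRUE, seed = seed + j,
                   num.threads = 1,
                   splitrule = if (j <= 2) "gini" else "extratrees",
                   mtry = if (j <= 2) NULL else 1L)
  })
}

cascade_layer_predict <- function(forests, x) {
  do.call(cbind, lapply(forests, function(f)
    stats::predict(f, data = data.frame(x),
                   num.threads = 1)$predictions))
}

fit_deep_forest_raw <- function(x, y, max_layers = 4L, trees = 100L,
                                cv_folds = 3L, seed = 1L) {
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cv_folds), nrow(x)))
  layers <- list()
  cur <- x
  best_acc <- -Inf
  for (l in seq_len(max_layers)) {
    # held-out accuracy of this layer via internal cross-validation
    acc <- 0
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      fs <- cascade_layer_fit(cur[tr, , drop = FALSE], y[tr], trees,
                              seed + 100L * l + k)
      pp <- cascade_layer_predict(fs, cur[!tr, , drop = FALSE])
      pos <- rowMeans(pp[, seq(2, ncol(pp), by = 2), drop = FALSE])
      acc <- acc + mean((pos > 0.5) == (y[!tr] == 1)) / cv_folds
    }
    if (acc <= best_acc + 1e-6) break
    best_acc <- acc
    forests <- cascade_layer_fit(cur, y, trees, seed + 100L * l)
    layers[[l]] <- forests
    aug <- cascade_layer_predict(forests, cur)
    colnames(aug) <- sprintf("prev_p%d", seq_len(ncol(aug)))
    cur <- cbind(x, aug)
  }
  list(layers = layers, config = list(trees = trees,
                                      max_layers = max_layers,
                                      n_layers = length(layers)),
       feature_dim = ncol(x))
}

deep_forest_predict <- function(model, x) {
  cur <- x
  prob <- NULL
  for (forests in model$layers) {
    pp <- cascade_layer_predict(forests, cur)
    prob <- rowMeans(pp[, seq(2, ncol(pp), by = 2), drop = FALSE])
    colnames(pp) <- sprintf("prev_p%d", seq_len(ncol(pp)))
    cur <- cbind(x, pp)
  }
  prob
}

#' Predict per-pixel vessel probabilities
#'
#' For a feature matrix, returns a probability vector. For a
#' `feature_stack` plus border mask, standardizes the stack with the
#' model's saved training parameters (unless it is already standardized),
#' verifies the feature manifest, and returns a probability map with border
#' pixels forced to zero.
#'
#' @param object a `vessel_model`.
#' @param newdata numeric matrix or `feature_stack`.
#' @param border_mask logical matrix (required for stacks).
#' @param ... unused.
#' @return numeric vector or probability matrix in \[0, 1\].
#' @export
predict.vessel_model <- function(object, newdata, border_mask = NULL,
                                 ...) {
  if (inherits(newdata, "feature_stack")) {
    if (is.null(border_mask)) stop("border_mask required for stacks")
    if (!identical(newdata$names, object$feature_names))
      stop("feature manifest mismatch between stack and model")
    if (is.null(newdata$standardization)) {
      if (is.null(object$standardization))
        stop("model carries no standardization parameters")
      newdata <- standardize(newdata, object$standardization)
    }
    x <- feature_matrix(newdata)
    p <- predict.vessel_model(object, x)
    pm <- matrix(p, nrow(border_mask), ncol(border_mask))
    pm[!border_mask] <- 0
    return(pm)
  }
  if (!identical(colnames(newdata), object$feature_names))
    stop("feature manifest mismatch")
  if (object$kind == "gbdt")
    predict_gbdt_raw(object$fitted, newdata)
  else
    deep_forest_predict(object$fitted, newdata)
}

#' @export
print.vessel_model <- function(x, ...) {
  cat("Vessel pixel classifier (", x$kind, "), ",
      length(x$feature_names), " features\n", sep = "")
  if (x$kind == "gbdt")
    cat(sprintf("  learning_rate %.3g, n_stages %d, max_depth %d\n",
                x$config$learning_rate, as.integer(x$config$n_stages),
                as.integer(x$config$max_depth)))
  else
    cat(sprintf("  cascade layers: %d (4 forests each)\n",
                x$config$n_layers))
  invisible(x)
}

#' @export
summary.vessel_model <- function(object, ...) {
  print(object)
  cat("  standardization saved:",
      !is.null(object$standardization), "\n")
  invisible(object)
}
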