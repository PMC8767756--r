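#' Training configuration for the deep feature extractor
#'
#' Defaults follow the segmentation-network training recipe used throughout
#' the package: Adam at learning rate 1e-3, mini-batches of 8, up to 100
#' epochs with early stopping after 15 epochs without validation
#' improvement, and affine augmentation (rotation within +/-20 degrees,
#' shifts up to 10% per axis, zoom up to 10%) applied with probability 0.7.
#'
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param max_epochs epoch cap.
#' @param patience early-stop patience in epochs (< `max_epochs`).
#' @param augment_prob probability of applying an affine augmentation.
#' @param rotation maximal rotation in degrees.
#' @param shift maximal shift as a fraction of image size per axis.
#' @param zoom maximal zoom-in as a fraction.
#' @param seed integer seed for weight init, shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch = 8L, max_epochs = 100L,
                         patience = 15L, augment_prob = 0.7,
                         rotation = 20, shift = 0.1, zoom = 0.1,
                         seed = 1L) {
  stopifnot(patience < max_epochs)
  structure(list(lr = lr, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 augment_prob = augment_prob, rotation = rotation,
                 shift = shift, zoom = zoom, seed = as.integer(seed)),
            class = "train_config")
}

#' Generalized Dice loss
#'
#' Two-class (vessel/background) generalized Dice:
#' `GD = 1 - 2 * sum_c w_c sum_p G_cp M_cp / sum_c w_c sum_p (G_cp + M_cp)`
#' with per-class weights `w_c = ((sum_p G_cp / t)^2 + eps)^-1`, `t = 2`
#' classes. The background maps are the complements `1 - G` and `1 - M`.
#' The inverse-squared-volume weights keep the sparse vessel class from
#' being swamped by the background.
#'
#' @param truth binary ground-truth matrix (1 = vessel).
#' @param pred predicted vessel-probability matrix in \[0, 1\].
#' @param eps weight stabilizer (default 1e-8).
#' @return scalar loss in \[0, 1\].
#' @export
gd_loss <- function(truth, pred, eps = 1e-8) {
  if (!identical(dim(truth), dim(pred))) stop("shape mismatch")
  t_classes <- 2
  g1 <- truth; g0 <- 1 - truth
  m1 <- pred; m0 <- 1 - pred
  w1 <- 1 / ((sum(g1) / t_classes)^2 + eps)
  w0 <- 1 / ((sum(g0) / t_classes)^2 + eps)
  num <- w1 * sum(g1 * m1) + w0 * sum(g0 * m0)
  den <- w1 * sum(g1 + m1) + w0 * sum(g0 + m0)
  1 - 2 * num / den
}

# gradient of gd_loss with respect to pred
gd_loss_grad <- function(truth, pred, eps = 1e-8) {
  t_classes <- 2
  g1 <- truth; g0 <- 1 - truth
  w1 <- 1 / ((sum(g1) / t_classes)^2 + eps)
  w0 <- 1 / ((sum(g0) / t_classes)^2 + eps)
  num <- w1 * sum(g1 * pred) + w0 * sum(g0 * (1 - pred))
  den <- w1 * sum(g1 + pred) + w0 * sum(g0 + 1 - pred)
  dnum <- w1 * g1 - w0 * g0
  dden <- w1 - w0
  -2 * (dnum * den - num * dden) / den^2
}

#' Paired affine augmentation of an image and its mask
#'
#' With probability `prob`, samples one affine transform (rotation, per-axis
#' shift with random sign, zoom-in) and applies it identically to the image
#' (bilinear interpolation, edge clamp) and the mask (nearest neighbour);
#' otherwise returns the pair unchanged. Draws from the current RNG stream,
#' so seeding is the caller's responsibility.
#'
#' @param image numeric matrix.
#' @param mask logical or 0/1 matrix of the same shape.
#' @param prob application probability.
#' @param rotation,shift,zoom transform ranges as in [train_config()].
#' @param force optional list to bypass sampling, e.g.
#'   `list(apply = TRUE, theta = 20, shift = c(0, 0), zoom = 1)` (theta in
#'   degrees); `list(apply = FALSE)` forces the identity branch.
#' @return list(`image`, `mask`, `applied`).
#' @export
augment_pair <- function(image, mask, prob = 0.7, rotation = 20,
                         shift = 0.1, zoom = 0.1, force = NULL) {
  if (is.null(force)) {
    apply_it <- stats::runif(1) < prob
    theta <- stats::runif(1, -rotation, rotation)
    sh <- stats::runif(2, 0, shift) * dim(image) *
      sample(c(-1, 1), 2, replace = TRUE)
    zm <- 1 + stats::runif(1, 0, zoom)
  } else {
    apply_it <- isTRUE(force$apply)
    theta <- if (is.null(force$theta)) 0 else force$theta
    sh <- if (is.null(force$shift)) c(0, 0) else force$shift
    zm <- if (is.null(force$zoom)) 1 else force$zoom
  }
  if (!apply_it)
    return(list(image = image, mask = mask, applied = FALSE))
  img2 <- affine_resample(image, theta * pi / 180, sh, zm, "bilinear")
  msk2 <- affine_resample(mask * 1.0, theta * pi / 180, sh, zm,
                          "nearest") > 0.5
  list(image = img2, mask = msk2, applied = TRUE)
}

# inverse-mapped affine resampling about the image centre
affine_resample <- function(img, theta, shift, zoom, interp = "bilinear") {
  d <- dim(img)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  rr <- matrix(seq_len(d[1]), d[1], d[2]) - cy
  cc <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE) - cx
  rr0 <- rr - shift[1]; cc0 <- cc - shift[2]
  src_r <- (cos(theta) * rr0 + sin(theta) * cc0) / zoom + cy
  src_c <- (-sin(theta) * rr0 + cos(theta) * cc0) / zoom + cx
  if (interp == "nearest") {
    ri <- pmin(pmax(round(src_r), 1), d[1])
    ci <- pmin(pmax(round(src_c), 1), d[2])
    return(matrix(img[cbind(as.vector(ri), as.vector(ci))], d[1], d[2]))
  }
  r0 <- pmin(pmax(floor(src_r), 1), d[1]); r1 <- pmin(r0 + 1, d[1])
  c0 <- pmin(pmax(floor(src_c), 1), d[2]); c1 <- pmin(c0 + 1, d[2])
  fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
  at <- function(ri, ci) matrix(img[cbind(as.vector(ri), as.vector(ci))],
                                d[1], d[2])
  (1 - fr) * ((1 - fc) * at(r0, c0) + fc * at(r0, c1)) +
    fr * ((1 - fc) * at(r1, c0) + fc * at(r1, c1))
}

#' Min/max normalization to \[0, 1\]
#'
#' @param img numeric matrix.
#' @return rescaled matrix (zeros if the image is constant).
#' @export
normalize_minmax <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] < 1e-12) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

## ---- minimal encoder-decoder built on im2col convolutions ----

shift_zero <- function(x, dr, dc) {
  d <- dim(x)
  out <- matrix(0, d[1], d[2])
  rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
  cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
  out[rs, cs] <- x[rs - dr, cs - dc, drop = FALSE]
  out
}

conv_offsets <- expand.grid(dr = -1:1, dc = -1:1)

# x: H x W x Cin array -> cols: (H*W) x (9*Cin) matrix
im2col3 <- function(x) {
  d <- dim(x)
  n <- d[1] * d[2]
  cols <- matrix(0, n, 9L * d[3])
  j <- 0L
  for (ci in seq_len(d[3])) {
    for (k in seq_len(9L)) {
      j <- j + 1L
      cols[, j] <- as.vector(shift_zero(x[, , ci],
                                        conv_offsets$dr[k],
                                        conv_offsets$dc[k]))
    }
  }
  cols
}

col2im3 <- function(dcols, hw, cin) {
  out <- array(0, c(hw[1], hw[2], cin))
  j <- 0L
  for (ci in seq_len(cin)) {
    acc <- matrix(0, hw[1], hw[2])
    for (k in seq_len(9L)) {
      j <- j + 1L
      acc <- acc + shift_zero(matrix(dcols[, j], hw[1], hw[2]),
                              -conv_offsets$dr[k], -conv_offsets$dc[k])
    }
    out[, , ci] <- acc
  }
  out
}

conv_fwd <- function(x, K, b) {
  d <- dim(x)
  cols <- im2col3(x)
  y <- cols %*% K
  y <- sweep(y, 2, b, "+")
  list(y = array(y, c(d[1], d[2], ncol(K))), cols = cols)
}

conv_bwd <- function(dy_arr, cols, K, hw, cin) {
  dy <- matrix(dy_arr, nrow = hw[1] * hw[2])
  list(dK = crossprod(cols, dy), db = colSums(dy),
       dx = col2im3(dy %*% t(K), hw, cin))
}

pool2_fwd <- function(x) {
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

pool2_bwd <- function(dy) {
  d <- dim(dy)
  dy[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
     drop = FALSE] / 4
}

up2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

up2_bwd <- function(dy) pool2_fwd(dy) * 4

unet_init <- function(seed) {
  set.seed(seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                nr, nc)
  list(K1 = he(9L, 8L), b1 = numeric(8),
       K2 = he(72L, 16L), b2 = numeric(16),
       K3 = he(216L, 16L), b3 = numeric(16),
       Kh = he(16L, 1L) / 4, bh = numeric(1))
}

# forward pass; returns activations needed for backprop and the 16 decoder
# maps (c3) that serve as deep features
unet_forward <- function(w, img) {
  d <- dim(img)
  x <- array(img, c(d[1], d[2], 1L))
  cv1 <- conv_fwd(x, w$K1, w$b1)
  a1 <- pmax(cv1$y, 0)
  p <- pool2_fwd(a1)
  cv2 <- conv_fwd(p, w$K2, w$b2)
  a2 <- pmax(cv2$y, 0)
  u <- up2_fwd(a2)
  cat3 <- array(c(u, a1), c(d[1], d[2], 24L))
  cv3 <- conv_fwd(cat3, w$K3, w$b3)
  a3 <- pmax(cv3$y, 0)
  z <- matrix(matrix(a3, ncol = 16L) %*% w$Kh + w$bh, d[1], d[2])
  prob <- 1 / (1 + exp(-z))
  list(prob = prob, a3 = a3, cv3 = cv3, cat3 = cat3, a2 = a2, cv2 = cv2,
       p = p, a1 = a1, cv1 = cv1, x = x, d = d)
}

unet_backward <- function(w, fwd, dprob) {
  d <- fwd$d
  dz <- dprob * fwd$prob * (1 - fwd$prob)
  da3_flat <- matrix(dz, ncol = 1L) %*% t(w$Kh)   # (HW) x 16
  dKh <- crossprod(matrix(fwd$a3, ncol = 16L), as.vector(dz))
  dbh <- sum(dz)
  da3 <- array(da3_flat, c(d[1], d[2], 16L)) * (fwd$cv3$y > 0)
  b3 <- conv_bwd(da3, fwd$cv3$cols, w$K3, d, 24L)
  du <- b3$dx[, , 1:16, drop = FALSE]
  da1_skip <- b3$dx[, , 17:24, drop = FALSE]
  da2 <- up2_bwd(du) * (fwd$cv2$y > 0)
  b2 <- conv_bwd(da2, fwd$cv2$cols, w$K2, dim(fwd$p)[1:2], 8L)
  da1 <- (pool2_bwd(b2$dx) + da1_skip) * (fwd$cv1$y > 0)
  b1 <- conv_bwd(da1, fwd$cv1$cols, w$K1, d, 1L)
  list(K1 = b1$dK, b1 = b1$db, K2 = b2$dK, b2 = b2$db,
       K3 = b3$dK, b3 = b3$db, Kh = dKh, bh = dbh)
}

adam_step <- function(w, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(w)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, state = state)
}

pad_even <- function(img) {
  d <- dim(img)
  pr <- d[1] %% 2L; pc <- d[2] %% 2L
  if (pr == 0 && pc == 0) return(list(img = img, pad = c(0L, 0L)))
  out <- matrix(0, d[1] + pr, d[2] + pc)
  out[seq_len(d[1]), seq_len(d[2])] <- img
  if (pr > 0) out[d[1] + 1L, seq_len(d[2])] <- img[d[1], ]  # reflect
  if (pc > 0) out[, d[2] + 1L] <- out[, d[2]]
  list(img = out, pad = c(pr, pc))
}

as_pair <- function(p) {
  img <- if (inherits(p$angiogram, "angiogram")) p$angiogram$pixels
         else if (!is.null(p$image)) p$image else p[[1]]
  msk <- if (inherits(p$mask, "vessel_mask")) p$mask$labels
         else if (is.list(p$mask)) p$mask$labels else p$mask
  list(image = normalize_minmax(img), mask = msk * 1.0)
}

#' Train the encoder-decoder deep feature extractor
#'
#' A compact segmentation network trained from scratch on synthetic pairs:
#' one 3x3 conv encoder stage (8 channels), 2x2 mean-pool, a 16-channel
#' bottleneck conv, nearest upsampling with a skip connection, a final
#' 16-channel decoder conv whose activations are the deep features, and a
#' 1x1 sigmoid head. Optimized with Adam on the generalized Dice loss, with
#' paired affine augmentation, early stopping on validation loss, and the
#' lowest-validation-loss weights returned. Images must have even height and
#' width (one pooling level).
#'
#' @param pairs list of training pairs; each element either
#'   `list(angiogram, mask)` from [generate_dataset()] or
#'   `list(image, mask)` of plain matrices.
#' @param config a [train_config()].
#' @param validation optional list of validation pairs; defaults to the
#'   training pairs (useful only for smoke tests).
#' @return object of class `unet_checkpoint`: `weights`, `config`,
#'   `history` (per-epoch train/validation loss), `best_epoch`,
#'   `epochs_run`.
#' @export
train_unet <- function(pairs, config = train_config(), validation = NULL) {
  if (length(pairs) == 0) stop("empty training set")
  pairs <- lapply(pairs, as_pair)
  val <- if (is.null(validation)) pairs else lapply(validation, as_pair)
  set.seed(config$seed)
  w <- unet_init(config$seed)
  zero_like <- lapply(w, function(p) p * 0)
  state <- list(m = zero_like, v = zero_like)
  best <- list(loss = Inf, w = w, epoch = 0L)
  history <- data.frame(epoch = integer(), train = numeric(),
                        val = numeric())
  tstep <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(pairs))
    ep_loss <- 0
    for (start in seq(1, length(ord), by = config$batch)) {
      idx <- ord[start:min(start + config$batch - 1L, length(ord))]
      gacc <- zero_like
      bloss <- 0
      for (i in idx) {
        aug <- augment_pair(pairs[[i]]$image, pairs[[i]]$mask,
                            prob = config$augment_prob,
                            rotation = config$rotation,
                            shift = config$shift, zoom = config$zoom)
        fwd <- unet_forward(w, aug$image)
        bloss <- bloss + gd_loss(aug$mask * 1.0, fwd$prob)
        g <- unet_backward(w, fwd, gd_loss_grad(aug$mask * 1.0, fwd$prob))
        for (nm in names(gacc))
          gacc[[nm]] <- gacc[[nm]] + g[[nm]] / length(idx)
      }
      tstep <- tstep + 1L
      upd <- adam_step(w, gacc, state, config$lr, tstep)
      w <- upd$w; state <- upd$state
      ep_loss <- ep_loss + bloss
    }
    val_loss <- mean(vapply(val, function(p)
      gd_loss(p$mask * 1.0, unet_forward(w, p$image)$prob), numeric(1)))
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train = ep_loss / length(pairs),
                                val = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, w = w, epoch = epoch)
    } else if (epoch - best$epoch >= config$patience) {
      break
    }
  }
  structure(list(weights = best$w, config = config, history = history,
                 best_epoch = best$epoch, epochs_run = nrow(history)),
            class = "unet_checkpoint")
}

#' @export
print.unet_checkpoint <- function(x, ...) {
  cat(sprintf(paste0("Encoder-decoder checkpoint: %d epochs run, best ",
                     "validation GD loss %.4f at epoch %d\n"),
              x$epochs_run, min(x$history$val), x$best_epoch))
  invisible(x)
}

#' Extract the 16 deep feature maps for an image
#'
#' Runs a pure forward pass (no parameter updates) and returns the
#' activation maps of the final decoder layer at input resolution. Images
#' with odd dimensions are reflect-padded to even size and the output
#' cropped back.
#'
#' @param checkpoint a trained [train_unet()] checkpoint.
#' @param image intensity matrix; min/max-normalized internally.
#' @return list of 16 matrices with the input's spatial shape.
#' @export
extract_deep_features <- function(checkpoint, image) {
  stopifnot(inherits(checkpoint, "unet_checkpoint"))
  d0 <- dim(image)
  pd <- pad_even(normalize_minmax(image))
  fwd <- unet_forward(checkpoint$weights, pd$img)
  lapply(seq_len(16L), function(k)
    fwd$a3[seq_len(d0[1]), seq_len(d0[2]), k])
}

#' Predict a vessel-probability map with the deep network head
#'
#' @param object a `unet_checkpoint`.
#' @param image intensity matrix.
#' @param ... unused.
#' @return probability matrix in \[0, 1\].
#' @export
predict.unet_checkpoint <- function(object, image, ...) {
  d0 <- dim(image)
  pd <- pad_even(normalize_minmax(image))
  unet_forward(object$weights, pd$img)$prob[seq_len(d0[1]),
                                            seq_len(d0[2])]
}
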