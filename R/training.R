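#' Baseline training: optimiser, schedule, augmentation, early stopping
#'
#' The planar networks are trained independently on 2D slices with Adam
#' (epsilon 1e-4), batch size 8, an initial learning rate of 1e-3 reduced by
#' a factor of 10 every 2 epochs down to a floor of 1e-5, online-style data
#' augmentation (translation, rotation, additive Gaussian noise, Gaussian
#' blur; one transform per augmented copy, parameters drawn uniformly from
#' closed intervals), a subject-level 90/10 train/validation split, and
#' early stopping on the validation combined loss with a patience of 25
#' epochs after an initial non-stopping pretraining phase.
#'
#' @name wmhda-training
NULL

#' Training configuration
#'
#' @param batch_size slices per batch.
#' @param lr_init,lr_factor,lr_step_epochs,lr_floor learning-rate schedule:
#'   `lr(e) = max(lr_floor, lr_init * lr_factor^floor(e / lr_step_epochs))`.
#' @param adam_eps Adam epsilon.
#' @param pretrain_epochs epochs before the patience criterion activates.
#' @param patience epochs to wait for validation improvement.
#' @param val_fraction fraction of subjects held out for validation.
#' @param max_epochs hard cap on epochs.
#' @param seed run seed (shuffling, augmentation, splits).
#' @export
train_config <- function(batch_size = 8, lr_init = 1e-3, lr_factor = 0.1,
                         lr_step_epochs = 2, lr_floor = 1e-5, adam_eps = 1e-4,
                         pretrain_epochs = 50, patience = 25,
                         val_fraction = 0.1, max_epochs = 200, seed = 0) {
  stopifnot(lr_floor > 0, lr_floor <= lr_init, patience >= 1,
            val_fraction > 0, val_fraction < 1, batch_size >= 1)
  structure(list(batch_size = batch_size, lr_init = lr_init,
                 lr_factor = lr_factor, lr_step_epochs = lr_step_epochs,
                 lr_floor = lr_floor, adam_eps = adam_eps,
                 pretrain_epochs = pretrain_epochs, patience = patience,
                 val_fraction = val_fraction, max_epochs = max_epochs,
                 seed = seed),
            class = "train_config")
}

#' Augmentation configuration
#'
#' Intervals are closed; parameters are drawn uniformly. Expansion factors
#' give the total dataset size multiple (original included): 10 for axial,
#' 6 for sagittal/coronal.
#'
#' @param translate_range in-plane offset interval (voxels).
#' @param rotate_range rotation interval (degrees).
#' @param noise_var_range additive Gaussian noise variance interval.
#' @param blur_sigma_range Gaussian filter sigma interval.
#' @param factor_axial,factor_sag_cor expansion factors per plane.
#' @export
augment_config <- function(translate_range = c(-10, 10),
                           rotate_range = c(-10, 10),
                           noise_var_range = c(0.01, 0.09),
                           blur_sigma_range = c(0.1, 0.3),
                           factor_axial = 10, factor_sag_cor = 6) {
  ord <- function(r) length(r) == 2 && r[1] <= r[2]
  stopifnot(ord(translate_range), ord(rotate_range), ord(noise_var_range),
            ord(blur_sigma_range), factor_axial >= 1, factor_sag_cor >= 1)
  structure(list(translate_range = translate_range,
                 rotate_range = rotate_range,
                 noise_var_range = noise_var_range,
                 blur_sigma_range = blur_sigma_range,
                 factor_axial = factor_axial, factor_sag_cor = factor_sag_cor),
            class = "augment_config")
}

#' Learning-rate schedule
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return learning rate `max(lr_floor, lr_init * lr_factor^floor(epoch /
#'   lr_step_epochs))`.
#' @export
lr_schedule <- function(epoch, config) {
  stopifnot(epoch >= 0)
  max(config$lr_floor,
      config$lr_init * config$lr_factor^floor(epoch / config$lr_step_epochs))
}

# rotate a 2D matrix about its centre; bilinear for images, nearest for labels
rotate2d <- function(mat, angle_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (abs(angle_deg) < 1e-12) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  th <- angle_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  gi <- matrix(seq_len(h), h, w); gj <- matrix(seq_len(w), h, w, byrow = TRUE)
  # inverse rotation of output coords into source coords
  si <- cos(th) * (gi - cy) + sin(th) * (gj - cx) + cy
  sj <- -sin(th) * (gi - cy) + cos(th) * (gj - cx) + cx
  if (method == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out <- matrix(0, h, w)
    out[ok] <- mat[cbind(ri[ok], rj[ok])]
    return(out)
  }
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    v <- matrix(0, h, w)
    v[ok] <- mat[cbind(ii[ok], jj[ok])]
    v
  }
  val(i0, j0) * (1 - fi) * (1 - fj) + val(i0 + 1, j0) * fi * (1 - fj) +
    val(i0, j0 + 1) * (1 - fi) * fj + val(i0 + 1, j0 + 1) * fi * fj
}

shift2d <- function(mat, di, dj) {
  if (di == 0 && dj == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  out <- matrix(0, h, w)
  src_i <- intersect(seq_len(h), seq_len(h) - di)
  src_j <- intersect(seq_len(w), seq_len(w) - dj)
  if (length(src_i) == 0 || length(src_j) == 0) return(out)
  out[src_i + di, src_j + dj] <- mat[src_i, src_j]
  out
}

blur2d <- function(mat, sigma) {
  if (sigma <= 1e-8) return(mat)
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  x <- array(mat, c(dim(mat), 1))
  x <- axis_conv(x, k, 1)
  x <- axis_conv(x, k, 2)
  x[, , 1]
}

#' Augment one (image, label) slice pair
#'
#' Draws one transform per call — translation, rotation, noise injection or
#' Gaussian blur, chosen uniformly — with its parameter drawn uniformly from
#' the configured closed interval. Geometric transforms are applied
#' identically to image channels (bilinear) and label (nearest,
#' re-binarised); noise and blur touch the image channels only.
#'
#' @param x image slice array `(H, W, C)`.
#' @param y binary label matrix `(H, W)`.
#' @param config an [augment_config()].
#' @param rng stream from [rng_make()].
#' @return list with augmented `x` and `y`.
#' @export
augment_sample <- function(x, y, config, rng) {
  stopifnot(length(dim(x)) == 3, identical(dim(x)[1:2], dim(y)[1:2]))
  kind <- rng_int(rng, 1, 1, 4)
  C <- dim(x)[3]
  if (kind == 1) {            # translation (integer in-plane offsets)
    di <- round(rng_unif(rng, 1, config$translate_range[1], config$translate_range[2]))
    dj <- round(rng_unif(rng, 1, config$translate_range[1], config$translate_range[2]))
    for (c in seq_len(C)) x[, , c] <- shift2d(x[, , c], di, dj)
    y <- shift2d(y, di, dj)
  } else if (kind == 2) {     # rotation
    th <- rng_unif(rng, 1, config$rotate_range[1], config$rotate_range[2])
    for (c in seq_len(C)) x[, , c] <- rotate2d(x[, , c], th, "bilinear")
    y <- (rotate2d(y, th, "nearest") > 0.5) * 1
  } else if (kind == 3) {     # additive Gaussian noise (image only)
    v <- rng_unif(rng, 1, config$noise_var_range[1], config$noise_var_range[2])
    if (v > 0) x <- x + array(rng_norm(rng, length(x), sd = sqrt(v)), dim(x))
  } else {                    # Gaussian blur (image only)
    s <- rng_unif(rng, 1, config$blur_sigma_range[1], config$blur_sigma_range[2])
    for (c in seq_len(C)) x[, , c] <- blur2d(x[, , c], s)
  }
  list(x = x, y = (y > 0.5) * 1)
}

#' Expand a slice dataset by augmentation
#'
#' Emits each original sample plus `factor - 1` augmented copies, where the
#' factor is 10 for the axial plane and 6 for sagittal/coronal (total size =
#' factor x input size).
#'
#' @param samples nonempty list of `list(x = (H,W,C), y = (H,W))` samples.
#' @param plane plane name (selects the factor).
#' @param config an [augment_config()].
#' @param seed seed of the augmentation stream.
#' @return expanded list of samples.
#' @export
expand_dataset <- function(samples, plane, config = augment_config(), seed = 0) {
  if (length(samples) == 0) stop("empty sample list")
  if (!plane %in% PLANES) stop("unknown plane: ", plane)
  factor <- if (plane == "axial") config$factor_axial else config$factor_sag_cor
  rng <- rng_make(seed)
  out <- vector("list", length(samples) * factor)
  j <- 0
  for (s in samples) {
    j <- j + 1; out[[j]] <- s
    for (k in seq_len(factor - 1)) {
      j <- j + 1
      out[[j]] <- augment_sample(s$x, s$y, config, rng)
    }
  }
  out
}

# slice dataset for one plane from a list of subjects
plane_dataset <- function(cohort, plane, resize_dims, crop_margin = 2) {
  out <- list()
  for (si in seq_along(cohort)) {
    pp <- preprocess_subject_plane(cohort[[si]], plane, resize_dims,
                                   crop_margin = crop_margin, keep = "brain")
    n <- dim(pp$x)[4]
    for (k in seq_len(n))
      out[[length(out) + 1]] <- list(x = pp$x[, , , k], y = pp$y[, , k],
                                     subject = si,
                                     subject_has_label = pp$has_label)
  }
  out
}

samples_to_batch <- function(samples, idx) {
  h <- dim(samples[[idx[1]]]$x)[1]; w <- dim(samples[[idx[1]]]$x)[2]
  C <- dim(samples[[idx[1]]]$x)[3]
  xb <- array(0, c(h, w, C, length(idx)))
  yb <- array(0, c(h, w, length(idx)))
  for (j in seq_along(idx)) {
    xb[, , , j] <- samples[[idx[j]]]$x
    yb[, , j] <- samples[[idx[j]]]$y
  }
  list(x = xb, y = yb)
}

# evaluation loss over a sample list (eval mode, batched)
dataset_loss <- function(net, samples, lw, batch_size = 8) {
  n <- length(samples)
  tot <- 0
  nb <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    bt <- samples_to_batch(samples, idx)
    p <- unet_forward(net, bt$x, train = FALSE)
    tot <- tot + combined_loss(p, bt$y, lw) * length(idx)
    nb <- nb + length(idx)
  }
  tot / nb
}

# one gradient step on a batch; returns the loss
seg_step <- function(net, xb, yb, opt, lw, lr) {
  layers <- unet_layers(net)
  zero_grads(layers)
  p <- unet_forward(net, xb, train = TRUE)
  lg <- combined_loss_grad(p, yb, lw)
  unet_backward(net, lg$dp)
  opt_step(opt, layers, lr = lr)
  lg$loss
}

#' Train a triplanar ensemble
#'
#' Each plane's network is trained independently on its own slice dataset.
#' The subject-level validation split avoids slice leakage; for a
#' single-subject cohort the split falls back to slice level. Early stopping
#' restores the best-validation checkpoint.
#'
#' @param ensemble a `triplanar_ensemble` (trained in place and returned).
#' @param cohort nonempty list of `wmhda_subject`.
#' @param config a [train_config()].
#' @param augment an [augment_config()]; `NULL` disables expansion.
#' @param lw a [loss_weights()].
#' @param verbose print per-epoch progress.
#' @return list with `ensemble` and `log` (data.frame: plane, epoch, lr,
#'   train_loss, val_loss).
#' @export
train_model <- function(ensemble, cohort, config = train_config(),
                        augment = augment_config(), lw = loss_weights(),
                        verbose = FALSE) {
  stopifnot(inherits(ensemble, "triplanar_ensemble"), length(cohort) >= 1)
  logs <- list()
  for (pi in seq_along(ensemble$planes)) {
    plane <- ensemble$planes[pi]
    net <- ensemble$nets[[plane]]
    seed_p <- derive_seed(config$seed, pi, tag = 11)
    samples <- plane_dataset(cohort, plane, ensemble$resize_dims[[plane]],
                             ensemble$crop_margin)
    n_sub <- length(cohort)
    if (n_sub >= 2) {
      n_val <- max(1, floor(config$val_fraction * n_sub))
      if (n_sub - n_val < 1) stop("cohort too small for a validation split")
      rngs <- rng_make(derive_seed(seed_p, 1, tag = 21))
      val_sub <- rng_sample(rngs, n_sub)[seq_len(n_val)]
      is_val <- vapply(samples, function(s) s$subject %in% val_sub, logical(1))
    } else {
      # single subject: slice-level split (documented fallback)
      rngs <- rng_make(derive_seed(seed_p, 1, tag = 21))
      ns <- length(samples)
      n_val <- max(1, floor(config$val_fraction * ns))
      vidx <- rng_sample(rngs, ns)[seq_len(n_val)]
      is_val <- seq_len(ns) %in% vidx
    }
    val_samples <- samples[is_val]
    tr_samples <- samples[!is_val]
    if (length(tr_samples) == 0 || length(val_samples) == 0)
      stop("cohort too small for a validation split")
    if (!is.null(augment))
      tr_samples <- expand_dataset(tr_samples, plane, augment,
                                   seed = derive_seed(seed_p, 2, tag = 22))
    opt <- opt_adam(eps = config$adam_eps)
    rngb <- rng_make(derive_seed(seed_p, 3, tag = 23))
    best_val <- Inf; best_params <- NULL; wait <- 0
    layers <- unet_layers(net)
    for (epoch in seq_len(config$max_epochs) - 1) {
      lr <- lr_schedule(epoch, config)
      ord <- rng_sample(rngb, length(tr_samples))
      tr_loss <- 0; nb <- 0
      for (b in seq_len(ceiling(length(ord) / config$batch_size))) {
        idx <- ord[((b - 1) * config$batch_size + 1):
                     min(b * config$batch_size, length(ord))]
        bt <- samples_to_batch(tr_samples, idx)
        tr_loss <- tr_loss + seg_step(net, bt$x, bt$y, opt, lw, lr)
        nb <- nb + 1
      }
      val_loss <- dataset_loss(net, val_samples, lw, config$batch_size)
      logs[[length(logs) + 1]] <- data.frame(
        plane = plane, epoch = epoch, lr = lr,
        train_loss = tr_loss / nb, val_loss = val_loss)
      if (verbose)
        message(sprintf("[%s] epoch %d lr %.1e train %.4f val %.4f",
                        plane, epoch, lr, tr_loss / nb, val_loss))
      if (val_loss < best_val - 1e-9) {
        best_val <- val_loss
        best_params <- layers_param_copy(layers)
        wait <- 0
      } else if (epoch + 1 > config$pretrain_epochs) {
        wait <- wait + 1
        if (wait >= config$patience) break
      }
    }
    if (!is.null(best_params)) layers_param_restore(layers, best_params)
  }
  list(ensemble = ensemble, log = do.call(rbind, logs))
}

#' Save / load an ensemble checkpoint
#'
#' Single-file checkpoint holding the architecture config, all parameters
#' and batch-norm running statistics.
#'
#' @param ensemble a `triplanar_ensemble`.
#' @param path file path.
#' @export
save_checkpoint <- function(ensemble, path) {
  payload <- list(config = ensemble$config, planes = ensemble$planes,
                  resize_dims = ensemble$resize_dims,
                  crop_margin = ensemble$crop_margin,
                  params = lapply(ensemble$nets, function(net)
                    layers_param_copy(unet_layers(net))))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  ens <- build_triplanar_ensemble(payload$config, payload$resize_dims,
                                  payload$planes, seed = 0,
                                  crop_margin = payload$crop_margin)
  for (plane in ens$planes)
    layers_param_restore(unet_layers(ens$nets[[plane]]), payload$params[[plane]])
  ens
}
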