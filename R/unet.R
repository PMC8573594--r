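#' Planar U-Net and triplanar ensemble
#'
#' A depth-trimmed 2D U-Net per anatomical plane: encoder levels of two
#' 3x3 conv + batch-norm + ReLU layers with 2x2 max pooling between levels,
#' a bottleneck block, and a symmetric decoder using bilinear upsampling +
#' convolution with skip connections, ending in a 1x1 projection to the two
#' classes (WMH / non-WMH) and a per-pixel softmax. The three planar
#' networks are trained independently; at prediction time the reassembled
#' 3D probability volumes are averaged.
#'
#' @name wmhda-model
NULL

#' Configuration of one planar U-Net
#'
#' Channel width at level `l` is `min(base_channels * 2^(l-1),
#' bottleneck_channels)`; the defaults give 128/256/512 at depth 3 (a
#' 512-channel bottleneck). Synthetic benchmarks use far smaller widths.
#'
#' @param in_channels input modalities (FLAIR + T1 = 2).
#' @param n_classes output classes (2).
#' @param depth number of resolution levels (>= 2, default 3).
#' @param base_channels channels at the first level.
#' @param bottleneck_channels cap at the coarsest level.
#' @return object of class `planar_unet_config`.
#' @export
planar_unet_config <- function(in_channels = 2, n_classes = 2, depth = 3,
                               base_channels = 128, bottleneck_channels = 512) {
  if (depth < 2) stop("depth must be >= 2")
  stopifnot(in_channels >= 1, n_classes >= 2, base_channels >= 1,
            bottleneck_channels >= base_channels)
  channels <- pmin(base_channels * 2^(seq_len(depth) - 1), bottleneck_channels)
  structure(list(in_channels = in_channels, n_classes = n_classes,
                 depth = depth, base_channels = base_channels,
                 bottleneck_channels = bottleneck_channels,
                 channels = channels),
            class = "planar_unet_config")
}

new_block <- function(cin, cout, rng) {
  B <- new.env(parent = emptyenv())
  B$conv1 <- nn_conv2d(cin, cout, 3, 1, rng)
  B$bn1 <- nn_bn2d(cout)
  B$conv2 <- nn_conv2d(cout, cout, 3, 1, rng)
  B$bn2 <- nn_bn2d(cout)
  B
}

block_fw <- function(B, x, train) {
  a <- bn_fw(B$bn1, conv_fw(B$conv1, x), train)
  B$m1 <- a > 0; a <- a * B$m1
  a <- bn_fw(B$bn2, conv_fw(B$conv2, a), train)
  B$m2 <- a > 0
  a * B$m2
}

block_bw <- function(B, dy) {
  dy <- conv_bw(B$conv2, bn_bw(B$bn2, dy * B$m2))
  dy <- conv_bw(B$conv1, bn_bw(B$bn1, dy * B$m1))
  B$m1 <- NULL; B$m2 <- NULL
  dy
}

block_layers <- function(B, prefix)
  stats::setNames(list(B$conv1, B$bn1, B$conv2, B$bn2),
                  paste0(prefix, c("_conv1", "_bn1", "_conv2", "_bn2")))

#' Build one planar U-Net
#'
#' Weight initialisation is He-normal from the given seed; two builds from
#' the same `(config, seed)` are bit-identical.
#'
#' @param config a [planar_unet_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `planar_unet` object (environment).
#' @export
build_planar_unet <- function(config, seed = 0) {
  stopifnot(inherits(config, "planar_unet_config"))
  rng <- rng_make(seed)
  d <- config$depth
  ch <- config$channels
  net <- new.env(parent = emptyenv())
  net$config <- config
  net$enc <- lapply(seq_len(d - 1), function(l)
    new_block(if (l == 1) config$in_channels else ch[l - 1], ch[l], rng))
  net$pools <- lapply(seq_len(d - 1), function(l) nn_maxpool2())
  net$bott <- new_block(ch[d - 1], ch[d], rng)
  # decoder level l receives upsampled ch[l+1], projects to ch[l], concats skip
  net$upconv <- lapply(seq_len(d - 1), function(l) nn_conv2d(ch[l + 1], ch[l], 3, 1, rng))
  net$dec <- lapply(seq_len(d - 1), function(l) new_block(2 * ch[l], ch[l], rng))
  net$out_conv <- nn_conv2d(ch[1], config$n_classes, 1, 0, rng)
  class(net) <- "planar_unet"
  net
}

# named list of every parameter-bearing layer, topological order
unet_layers <- function(net) {
  d <- net$config$depth
  out <- list()
  for (l in seq_len(d - 1)) out <- c(out, block_layers(net$enc[[l]], paste0("enc", l)))
  out <- c(out, block_layers(net$bott, "bott"))
  for (l in rev(seq_len(d - 1))) {
    out <- c(out, stats::setNames(list(net$upconv[[l]]), paste0("upconv", l)))
    out <- c(out, block_layers(net$dec[[l]], paste0("dec", l)))
  }
  c(out, list(out_conv = net$out_conv))
}

#' Total trainable parameter count of a planar network
#' @param net a `planar_unet`.
#' @export
unet_n_parameters <- function(net)
  sum(vapply(unet_layers(net), function(L)
    sum(vapply(L$param_names, function(p) length(L[[p]]), numeric(1))), numeric(1)))

#' Forward pass of a planar U-Net
#'
#' @param net a `planar_unet`.
#' @param x input batch, array `(H, W, in_channels, N)`; `H` and `W` must be
#'   divisible by `2^(depth-1)`.
#' @param train logical; batch statistics and caches for backprop when TRUE.
#' @return probability array `(H, W, n_classes, N)`; per-pixel softmax.
#'   Feature taps are available afterwards as `net$tap_bottleneck` (coarsest
#'   encoder output) and `net$tap_decoder` (final decoder output, the layer
#'   before the label predictor).
#' @export
unet_forward <- function(net, x, train = FALSE) {
  d <- net$config$depth
  sp <- dim(x)[1:2]
  if (any(sp %% 2^(d - 1) != 0))
    stop("input dims must be divisible by ", 2^(d - 1))
  a <- x
  skips <- vector("list", d - 1)
  for (l in seq_len(d - 1)) {
    a <- block_fw(net$enc[[l]], a, train)
    skips[[l]] <- a
    a <- pool_fw(net$pools[[l]], a)
  }
  a <- block_fw(net$bott, a, train)
  net$tap_bottleneck <- a
  net$up_in_dims <- list()
  for (l in rev(seq_len(d - 1))) {
    tgt <- dim(skips[[l]])[1:2]
    net$up_in_dims <- c(net$up_in_dims, list(dim(a)[1:2]))
    a <- resize_bilinear4d(a, tgt[1], tgt[2])
    a <- conv_fw(net$upconv[[l]], a, keep_cache = train)
    U <- net$upconv[[l]]; U$mrelu <- a > 0
    a <- a * U$mrelu
    dd <- dim(a)
    cat_a <- array(0, c(dd[1], dd[2], dd[3] * 2, dd[4]))
    cat_a[, , seq_len(dd[3]), ] <- a
    cat_a[, , dd[3] + seq_len(dd[3]), ] <- skips[[l]]
    if (l == 1) net$tap_label_in <- cat_a  # input of the label predictor
    a <- block_fw(net$dec[[l]], cat_a, train)
  }
  net$tap_decoder <- a
  logits <- conv_fw(net$out_conv, a, keep_cache = train)
  p <- softmax_channels(logits)
  if (train) net$p <- p
  p
}

#' Backward pass of a planar U-Net
#'
#' Accumulates parameter gradients given the gradient of the loss with
#' respect to the softmax probabilities. Optional gradients can be injected
#' at the feature taps (used by the adversarial adaptation strategies: the
#' domain head's gradient, scaled by the reversal factor, enters here).
#'
#' @param net network after `unet_forward(..., train = TRUE)`.
#' @param dprob gradient wrt probabilities, same shape; may be `NULL` when
#'   only injected gradients should flow.
#' @param inject_decoder gradient added at the final-decoder tap.
#' @param inject_bottleneck gradient added at the bottleneck tap.
#' @param inject_label_in gradient added at the label-predictor input tap
#'   (the concatenation feeding the final decoder block).
#' @return gradient with respect to the input batch, invisibly.
#' @export
unet_backward <- function(net, dprob, inject_decoder = NULL,
                          inject_bottleneck = NULL, inject_label_in = NULL) {
  d <- net$config$depth
  if (!is.null(dprob)) {
    dz <- softmax_channels_bw(net$p, dprob)
    da <- conv_bw(net$out_conv, dz)
  } else {
    da <- array(0, dim(net$tap_decoder))
  }
  if (!is.null(inject_decoder)) da <- da + inject_decoder
  dskips <- vector("list", d - 1)
  for (l in seq_len(d - 1)) {   # decoder levels, innermost (1) outwards
    da <- block_bw(net$dec[[l]], da)
    if (l == 1 && !is.null(inject_label_in)) da <- da + inject_label_in
    cc <- dim(da)[3] / 2
    dup <- da[, , seq_len(cc), , drop = FALSE]
    dskips[[l]] <- da[, , cc + seq_len(cc), , drop = FALSE]
    U <- net$upconv[[l]]
    dup <- conv_bw(U, dup * U$mrelu)
    U$mrelu <- NULL
    pre <- net$up_in_dims[[d - l]]  # up_in_dims stored outermost first
    da <- resize_bilinear4d(dup, pre[1], pre[2], transpose = TRUE)
  }
  if (!is.null(inject_bottleneck)) da <- da + inject_bottleneck
  da <- block_bw(net$bott, da)
  for (l in rev(seq_len(d - 1))) {
    da <- pool_bw(net$pools[[l]], da)
    da <- da + dskips[[l]]
    da <- block_bw(net$enc[[l]], da)
  }
  net$p <- NULL
  invisible(da)
}

# ---- losses ---------------------------------------------------------------

as_label_array <- function(labels, pdim) {
  if (length(dim(labels)) == 2) dim(labels) <- c(dim(labels), 1)
  if (!identical(as.integer(dim(labels)), as.integer(pdim[c(1, 2, 4)])))
    stop("label shape does not match probabilities")
  labels
}

#' Per-voxel weights for the weighted cross-entropy
#'
#' Default scheme: inverse class frequency within the batch, normalised to
#' mean 1 (a pluggable stand-in for the class-imbalance weighting of the
#' baseline method; the exact scheme lives in prior work).
#'
#' @param labels binary array `(H, W, N)`.
#' @param mode `"inverse_freq"` or `"none"`.
#' @return array of non-negative weights, same shape as `labels`.
#' @export
voxel_weights <- function(labels, mode = c("inverse_freq", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(array(1, dim(labels)))
  n <- length(labels); n1 <- sum(labels); n0 <- n - n1
  w1 <- if (n1 > 0) n / (2 * n1) else 1
  w0 <- if (n0 > 0) n / (2 * n0) else 1
  array(w0 + (w1 - w0) * (labels > 0), dim(labels))
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of `weight * (-log p_true)`, linear in the weights.
#'
#' @param probabilities array `(H, W, 2, N)`, per-pixel softmax output.
#' @param labels binary array `(H, W, N)` (1 = WMH).
#' @param weights non-negative per-voxel weights, shape of `labels`;
#'   `NULL` = unweighted.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probabilities, labels, weights = NULL) {
  ce_loss_grad(probabilities, labels, weights, want_grad = FALSE)$loss
}

ce_loss_grad <- function(p, labels, weights = NULL, want_grad = TRUE) {
  dimp <- dim(p)
  y <- as_label_array(labels, dimp)
  if (is.null(weights)) weights <- array(1, dim(y))
  if (!identical(dim(weights), dim(y))) stop("weight shape mismatch")
  if (any(weights < 0)) stop("weights must be >= 0")
  eps <- 1e-12
  yv <- as.vector(y)
  p2 <- as.vector(p[, , 2, ]); p1 <- as.vector(p[, , 1, ])
  ptrue <- p2 * yv + p1 * (1 - yv)
  npix <- length(yv)
  loss <- sum(as.vector(weights) * -log(pmax(ptrue, eps))) / npix
  if (!want_grad) return(list(loss = loss))
  dp <- array(0, dimp)
  g <- -as.vector(weights) / pmax(ptrue, eps) / npix
  dp[, , 2, ] <- g * yv
  dp[, , 1, ] <- g * (1 - yv)
  list(loss = loss, dp = dp)
}

#' Soft Dice loss on the WMH channel
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)` computed on the
#' lesion-probability channel; counteracts the extreme class imbalance
#' between lesion and healthy tissue.
#'
#' @inheritParams weighted_cross_entropy
#' @param eps smoothing constant.
#' @return scalar loss in `[0, 1]`.
#' @export
soft_dice_loss <- function(probabilities, labels, eps = 1e-6) {
  dice_loss_grad(probabilities, labels, eps, want_grad = FALSE)$loss
}

dice_loss_grad <- function(p, labels, eps = 1e-6, want_grad = TRUE) {
  dimp <- dim(p)
  y <- as.vector(as_label_array(labels, dimp))
  p2 <- as.vector(p[, , 2, ])
  num <- 2 * sum(p2 * y) + eps
  den <- sum(p2) + sum(y) + eps
  loss <- 1 - num / den
  if (!want_grad) return(list(loss = loss))
  dp <- array(0, dimp)
  dp[, , 2, ] <- -(2 * y * den - num) / den^2
  list(loss = loss, dp = dp)
}

#' Loss weighting for the combined segmentation loss
#' @param lambda_ce,lambda_dice non-negative term weights (not both zero).
#' @param voxel_weight_mode per-voxel CE weight scheme, see [voxel_weights()].
#' @export
loss_weights <- function(lambda_ce = 1, lambda_dice = 1,
                         voxel_weight_mode = "inverse_freq") {
  if (lambda_ce < 0 || lambda_dice < 0) stop("loss weights must be >= 0")
  if (lambda_ce == 0 && lambda_dice == 0) stop("loss weights cannot both be zero")
  structure(list(lambda_ce = lambda_ce, lambda_dice = lambda_dice,
                 voxel_weight_mode = voxel_weight_mode),
            class = "loss_weights")
}

#' Combined segmentation loss: weighted cross-entropy + soft Dice
#'
#' @inheritParams weighted_cross_entropy
#' @param weights a [loss_weights()] object.
#' @return scalar `lambda_ce * wCE + lambda_dice * Dice`.
#' @export
combined_loss <- function(probabilities, labels, weights = loss_weights()) {
  combined_loss_grad(probabilities, labels, weights, want_grad = FALSE)$loss
}

combined_loss_grad <- function(p, labels, weights = loss_weights(),
                               want_grad = TRUE) {
  stopifnot(inherits(weights, "loss_weights"))
  y <- as_label_array(labels, dim(p))
  vw <- voxel_weights(y, weights$voxel_weight_mode)
  ce <- if (weights$lambda_ce > 0) ce_loss_grad(p, y, vw, want_grad) else
    list(loss = 0, dp = 0)
  di <- if (weights$lambda_dice > 0) dice_loss_grad(p, y, want_grad = want_grad) else
    list(loss = 0, dp = 0)
  out <- list(loss = weights$lambda_ce * ce$loss + weights$lambda_dice * di$loss,
              ce = ce$loss, dice = di$loss)
  if (want_grad)
    out$dp <- weights$lambda_ce * (ce$dp %||% 0) + weights$lambda_dice * (di$dp %||% 0)
  out
}

# ---- triplanar ensemble ---------------------------------------------------

#' Build a triplanar U-Net ensemble
#'
#' One planar network per requested plane, architecturally identical (input
#' dims differ only at runtime). The benchmark can restrict `planes` to a
#' subset to fit CPU budgets.
#'
#' @param config a [planar_unet_config()] shared by the planes.
#' @param resize_dims per-plane slice dims, see [plane_resize_dims()].
#' @param planes character subset of axial/sagittal/coronal.
#' @param seed root seed; per-plane seeds are split from it.
#' @param crop_margin FOV crop margin in voxels.
#' @return object of class `triplanar_ensemble`.
#' @export
build_triplanar_ensemble <- function(config = planar_unet_config(),
                                     resize_dims = plane_resize_dims(),
                                     planes = PLANES, seed = 0,
                                     crop_margin = 2) {
  stopifnot(all(planes %in% PLANES), length(planes) >= 1)
  nets <- lapply(seq_along(planes), function(i)
    build_planar_unet(config, derive_seed(seed, i, tag = 77)))
  names(nets) <- planes
  structure(list(nets = nets, planes = planes, config = config,
                 resize_dims = resize_dims, crop_margin = crop_margin),
            class = "triplanar_ensemble")
}

# forward a (possibly large) slice stack in minibatches, eval mode
predict_slices <- function(net, x, batch = 8) {
  n <- dim(x)[4]
  p2 <- vector("list", ceiling(n / batch))
  for (b in seq_along(p2)) {
    idx <- ((b - 1) * batch + 1):min(b * batch, n)
    p <- unet_forward(net, x[, , , idx, drop = FALSE], train = FALSE)
    p2[[b]] <- p[, , 2, , drop = FALSE]
  }
  out <- array(0, c(dim(x)[1:2], 1, n))
  pos <- 1
  for (b in seq_along(p2)) {
    k <- dim(p2[[b]])[4]
    out[, , 1, pos:(pos + k - 1)] <- p2[[b]]
    pos <- pos + k
  }
  out
}

#' Predict a subject's 3D WMH probability volume
#'
#' Per plane: preprocess, slice, forward, reassemble to the original
#' geometry; the final volume is the arithmetic mean of the per-plane
#' probability volumes.
#'
#' @param ensemble a `triplanar_ensemble`.
#' @param subject a `wmhda_subject`.
#' @return 3D array of WMH probabilities in `[0, 1]`, original geometry.
#' @export
predict_volume <- function(ensemble, subject) {
  stopifnot(inherits(ensemble, "triplanar_ensemble"))
  vols <- lapply(ensemble$planes, function(plane) {
    pp <- preprocess_subject_plane(subject, plane,
                                   ensemble$resize_dims[[plane]],
                                   crop_margin = ensemble$crop_margin,
                                   keep = "all")
    p2 <- predict_slices(ensemble$nets[[plane]], pp$x)
    st <- pp$template_stack
    st$slices <- lapply(seq_len(dim(p2)[4]), function(k) p2[, , 1, k])
    assemble_probability_volume(st)
  })
  Reduce(`+`, vols) / length(vols)
}

#' Threshold a probability volume into a binary mask
#'
#' @param prob probability array.
#' @param threshold scalar in `(0, 1)`; voxels with `prob >= threshold`
#'   become lesion.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  (prob >= threshold) * 1
}

#' Deep-copy an ensemble (networks are mutable environments)
#' @param ensemble a `triplanar_ensemble`.
#' @export
clone_ensemble <- function(ensemble) {
  out <- ensemble
  out$nets <- lapply(ensemble$nets, function(net) {
    net2 <- build_planar_unet(net$config, seed = 0)
    layers_param_restore(unet_layers(net2), layers_param_copy(unet_layers(net)))
    net2
  })
  out
}
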