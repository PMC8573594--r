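#' Domain-adversarial training (DANN / semi-DANN)
#'
#' A domain predictor is attached at the coarsest encoder level (the
#' 512-channel bottleneck in the full-size network) behind a gradient
#' reversal layer: forward it is the identity, backward it multiplies the
#' domain-loss gradient by `-lambda`, so the feature extractor is pushed to
#' make domains indistinguishable while the label predictor keeps the
#' features useful for segmentation. The unsupervised variant uses lesion
#' labels from the source domain only; the semi-supervised variant adds a
#' small labelled fraction of target subjects.
#'
#' @name wmhda-adapt-dann
NULL

#' Gradient reversal layer
#'
#' `grad_reverse()` is the identity in the forward pass;
#' `grad_reverse_grad()` is its backward rule: the upstream gradient scaled
#' by `-lambda`. The training loops apply the pair explicitly (the domain
#' head trains on the positive gradient, the feature extractor receives the
#' reversed one).
#'
#' @param activations any numeric array.
#' @param lambda non-negative reversal scale.
#' @export
grad_reverse <- function(activations, lambda = 1) {
  stopifnot(lambda >= 0)
  activations
}

#' @rdname grad_reverse
#' @param upstream gradient flowing back into the reversal layer.
#' @export
grad_reverse_grad <- function(upstream, lambda = 1) {
  stopifnot(lambda >= 0)
  -lambda * upstream
}

#' DANN configuration
#'
#' @param grl_lambda gradient-reversal scale (constant; the original
#'   formulation leaves it unstated, 1.0 is the default).
#' @param proj_channels 1x1 projection widths before the FC stack.
#' @param fc_widths fully connected widths (paper-printed: 1024, 512, 32).
#' @param dropout dropout probability between FC layers.
#' @param domain_lr,domain_momentum momentum-SGD settings of the domain head.
#' @param main_lr initial learning rate of the main (Adam) path.
#' @param semi_fraction fraction of labelled target subjects (0 =
#'   unsupervised, 0.25 = the semi-supervised default).
#' @export
dann_config <- function(grl_lambda = 1.0, proj_channels = c(128, 64),
                        fc_widths = c(1024, 512, 32), dropout = 0.2,
                        domain_lr = 1e-3, domain_momentum = 0.9,
                        main_lr = 1e-3, semi_fraction = 0) {
  stopifnot(grl_lambda >= 0, dropout >= 0, dropout < 1,
            semi_fraction >= 0, semi_fraction <= 1,
            length(proj_channels) == 2, length(fc_widths) == 3)
  structure(list(grl_lambda = grl_lambda, proj_channels = proj_channels,
                 fc_widths = fc_widths, dropout = dropout,
                 domain_lr = domain_lr, domain_momentum = domain_momentum,
                 main_lr = main_lr, semi_fraction = semi_fraction),
            class = "dann_config")
}

# ---- generic head: sequence of pool / 1x1 conv / flatten / linear ops -----

head_new <- function() {
  h <- new.env(parent = emptyenv())
  h$ops <- list()
  h
}

head_add <- function(h, type, layer = NULL) {
  h$ops[[length(h$ops) + 1]] <- list(type = type, layer = layer)
  invisible(h)
}

head_layers <- function(h) {
  out <- list()
  for (i in seq_along(h$ops)) {
    L <- h$ops[[i]]$layer
    if (!is.null(L) && length(L$param_names) > 0)
      out[[paste0("head", i)]] <- L
  }
  out
}

#' Run a domain-predictor head forward / backward
#'
#' Heads are small op sequences (pool / 1x1 conv / flatten / FC / dropout /
#' softmax). `head_forward` returns the `(n, 2)` row-stochastic domain
#' predictions; `head_backward` backpropagates a gradient on those
#' predictions, accumulates the head's parameter gradients and returns the
#' gradient with respect to the head's input features.
#'
#' @param h a head from [build_domain_head()] or [build_du_domain_head()].
#' @param x input feature array `(H, W, C, N)`.
#' @param train enable dropout and caching for backprop.
#' @export
head_forward <- function(h, x, train = FALSE) {
  for (op in h$ops) {
    x <- switch(op$type,
      pool = pool_fw(op$layer, x),
      conv = conv_fw(op$layer, x),
      relu4 = { op$layer$m <- x > 0; x * op$layer$m },
      flatten = { op$layer$xdim <- dim(x)
                  t(matrix(x, prod(dim(x)[1:3]), dim(x)[4])) },
      linear = linear_fw(op$layer, x),
      relu = { op$layer$m <- x > 0; x * op$layer$m },
      dropout = dropout_fw(op$layer, x, train),
      softmax = { op$layer$p <- softmax_rows(x); op$layer$p },
      stop("unknown op ", op$type))
  }
  x
}

#' @rdname head_forward
#' @param dy gradient with respect to the head output.
#' @export
head_backward <- function(h, dy) {
  for (op in rev(h$ops)) {
    dy <- switch(op$type,
      pool = pool_bw(op$layer, dy),
      conv = conv_bw(op$layer, dy),
      relu4 = dy * op$layer$m,
      flatten = array(t(dy), op$layer$xdim),
      linear = linear_bw(op$layer, dy),
      relu = dy * op$layer$m,
      dropout = dropout_bw(op$layer, dy),
      softmax = softmax_rows_bw(op$layer$p, dy))
  }
  dy
}

cache_env <- function() new.env(parent = emptyenv())

#' Build the DANN domain-predictor head
#'
#' Sequence: 2x2 max-pool, 1x1 conv to `proj_channels[1]`, 1x1 conv to
#' `proj_channels[2]`, flatten, FC `fc_widths[1]`, dropout, FC
#' `fc_widths[2]`, dropout, FC `fc_widths[3]`, then a linear projection to
#' the 2 domains and a softmax (the final 2-way projection is implied by the
#' printed architecture and added explicitly).
#'
#' @param input_dims bottleneck tap dims `(h, w, channels)`.
#' @param config a [dann_config()].
#' @param seed weight-init seed.
#' @return a domain head usable with [head_forward()].
#' @export
build_domain_head <- function(input_dims, config = dann_config(), seed = 0) {
  h0 <- input_dims[1]; w0 <- input_dims[2]; ch <- input_dims[3]
  if (h0 %% 2 != 0 || w0 %% 2 != 0)
    stop("incompatible tap shape for 2x2 pooling: ", h0, "x", w0)
  rng <- rng_make(seed)
  h <- head_new()
  head_add(h, "pool", nn_maxpool2())
  head_add(h, "conv", nn_conv2d(ch, config$proj_channels[1], 1, 0, rng))
  head_add(h, "relu4", cache_env())
  head_add(h, "conv", nn_conv2d(config$proj_channels[1], config$proj_channels[2], 1, 0, rng))
  head_add(h, "relu4", cache_env())
  head_add(h, "flatten", cache_env())
  flat <- (h0 / 2) * (w0 / 2) * config$proj_channels[2]
  head_add(h, "linear", nn_linear(flat, config$fc_widths[1], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "dropout", nn_dropout(config$dropout, rng_make(derive_seed(seed, 1, 41))))
  head_add(h, "linear", nn_linear(config$fc_widths[1], config$fc_widths[2], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "dropout", nn_dropout(config$dropout, rng_make(derive_seed(seed, 2, 41))))
  head_add(h, "linear", nn_linear(config$fc_widths[2], config$fc_widths[3], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "linear", nn_linear(config$fc_widths[3], 2, rng))
  head_add(h, "softmax", cache_env())
  h
}

# domain cross-entropy on (N, 2) row-stochastic predictions, labels in {0,1}
domain_ce_grad <- function(q, d, want_grad = TRUE) {
  n <- nrow(q)
  idx <- cbind(seq_len(n), d + 1L)
  eps <- 1e-12
  loss <- mean(-log(pmax(q[idx], eps)))
  out <- list(loss = loss,
              accuracy = mean((q[, 2] > 0.5) == (d == 1)))
  if (want_grad) {
    dq <- matrix(0, n, 2)
    dq[idx] <- -1 / (n * pmax(q[idx], eps))
    out$dq <- dq
  }
  out
}

#' Select the labelled target subset for semi-supervised DANN
#'
#' `floor(fraction * n)` subjects drawn uniformly without replacement.
#'
#' @param subjects list (or vector) of target training subjects.
#' @param fraction labelled fraction in `[0, 1]`.
#' @param seed seed of the draw.
#' @return integer indices of the labelled subjects (empty when fraction 0).
#' @export
select_semi_subset <- function(subjects, fraction, seed = 0) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- length(subjects)
  k <- floor(fraction * n)
  if (k == 0) return(integer(0))
  rng <- rng_make(derive_seed(seed, 7, tag = 42))
  sort(rng_sample(rng, n)[seq_len(k)])
}

# mixed-domain slice pools for adversarial training of one plane.
# Target lesion labels are kept ONLY for the labelled subset: the
# unsupervised path cannot read them because they are never materialised.
adversarial_samples <- function(source_cohort, target_cohort, plane,
                                resize_dims, crop_margin, labelled_target_idx) {
  src <- plane_dataset(source_cohort, plane, resize_dims, crop_margin)
  for (i in seq_along(src)) { src[[i]]$domain <- 0L; src[[i]]$has_label <- TRUE }
  tgt <- plane_dataset(target_cohort, plane, resize_dims, crop_margin)
  for (i in seq_along(tgt)) {
    tgt[[i]]$domain <- 1L
    tgt[[i]]$has_label <- (tgt[[i]]$subject %in% labelled_target_idx) &&
      isTRUE(tgt[[i]]$subject_has_label)
    if (!tgt[[i]]$has_label) tgt[[i]]$y <- NULL
  }
  list(source = src, target = tgt)
}

# assemble a mixed batch; returns x, y (labelled only), lab_idx, domains
mixed_batch <- function(src_samples, tgt_samples, idx_s, idx_t) {
  all <- c(src_samples[idx_s], tgt_samples[idx_t])
  h <- dim(all[[1]]$x)[1]; w <- dim(all[[1]]$x)[2]; C <- dim(all[[1]]$x)[3]
  n <- length(all)
  xb <- array(0, c(h, w, C, n))
  dom <- integer(n)
  lab_idx <- integer(0)
  ys <- list()
  for (j in seq_len(n)) {
    xb[, , , j] <- all[[j]]$x
    dom[j] <- all[[j]]$domain
    if (isTRUE(all[[j]]$has_label)) {
      lab_idx <- c(lab_idx, j)
      ys[[length(ys) + 1]] <- all[[j]]$y
    }
  }
  yb <- NULL
  if (length(lab_idx) > 0) {
    yb <- array(0, c(h, w, length(lab_idx)))
    for (j in seq_along(ys)) yb[, , j] <- ys[[j]]
  }
  list(x = xb, y = yb, lab_idx = lab_idx, domains = dom)
}

#' Train a DANN (or semi-DANN) adapted ensemble
#'
#' Each step draws a 50/50 mixed-domain batch; the segmentation loss is
#' computed on label-available samples only (all source slices, plus the
#' labelled target subset when `semi_fraction > 0`), the domain
#' cross-entropy on all samples. The main path uses Adam with the baseline
#' schedule started at `main_lr`; the domain head uses momentum SGD. The
#' feature extractor receives the reversed, `-lambda`-scaled domain
#' gradient at the bottleneck.
#'
#' @param ensemble a `triplanar_ensemble` (typically source-pretrained);
#'   adapted in place and returned.
#' @param source_cohort labelled source subjects.
#' @param target_cohort target subjects (labels read only for the
#'   semi-supervised subset).
#' @param dcfg a [dann_config()].
#' @param tcfg a [train_config()] (epochs, batch size, schedule shape).
#' @param lw segmentation [loss_weights()].
#' @param epochs number of adaptation epochs (defaults to
#'   `tcfg$max_epochs`).
#' @return list with `ensemble`, `heads` (per plane) and `log` (per epoch:
#'   seg loss, domain loss, training domain accuracy, validation domain
#'   accuracy).
#' @export
train_dann <- function(ensemble, source_cohort, target_cohort,
                       dcfg = dann_config(), tcfg = train_config(),
                       lw = loss_weights(), epochs = NULL) {
  stopifnot(length(source_cohort) >= 1, length(target_cohort) >= 1)
  epochs <- epochs %||% tcfg$max_epochs
  labelled_idx <- select_semi_subset(target_cohort, dcfg$semi_fraction,
                                     seed = tcfg$seed)
  heads <- list()
  logs <- list()
  for (pi in seq_along(ensemble$planes)) {
    plane <- ensemble$planes[pi]
    net <- ensemble$nets[[plane]]
    seed_p <- derive_seed(tcfg$seed, pi, tag = 51)
    pools <- adversarial_samples(source_cohort, target_cohort, plane,
                                 ensemble$resize_dims[[plane]],
                                 ensemble$crop_margin, labelled_idx)
    # validation slices for the domain-accuracy monitor
    rngv <- rng_make(derive_seed(seed_p, 1, tag = 52))
    nval <- function(pool) max(1, floor(0.1 * length(pool)))
    vs <- rng_sample(rngv, length(pools$source))[seq_len(nval(pools$source))]
    vt <- rng_sample(rngv, length(pools$target))[seq_len(nval(pools$target))]
    val_s <- pools$source[vs]; val_t <- pools$target[vt]
    src <- pools$source[-vs]; tgt <- pools$target[-vt]
    if (length(src) == 0 || length(tgt) == 0) stop("cohorts too small")

    d <- net$config$depth
    rd <- ensemble$resize_dims[[plane]]
    bdim <- c(rd / 2^(d - 1), net$config$channels[d])
    head <- build_domain_head(bdim, dcfg, seed = derive_seed(seed_p, 2, 53))
    heads[[plane]] <- head
    opt_main <- opt_adam(eps = tcfg$adam_eps)
    opt_dom <- opt_sgdm(lr = dcfg$domain_lr, momentum = dcfg$domain_momentum)
    hlayers <- head_layers(head)
    ulayers <- unet_layers(net)
    rngb <- rng_make(derive_seed(seed_p, 3, tag = 54))
    half <- max(1, floor(tcfg$batch_size / 2))
    steps <- ceiling(max(length(src), length(tgt)) / half)
    for (epoch in seq_len(epochs) - 1) {
      lr <- max(tcfg$lr_floor,
                dcfg$main_lr * tcfg$lr_factor^floor(epoch / tcfg$lr_step_epochs))
      ord_s <- rng_sample(rngb, length(src), size = steps * half, replace = TRUE)
      ord_t <- rng_sample(rngb, length(tgt), size = steps * half, replace = TRUE)
      seg_sum <- 0; seg_n <- 0; dom_sum <- 0; acc_sum <- 0
      for (st in seq_len(steps)) {
        take <- ((st - 1) * half + 1):(st * half)
        bt <- mixed_batch(src, tgt, ord_s[take], ord_t[take])
        if (length(bt$lab_idx) == 0) stop("no label-available samples in batch")
        zero_grads(ulayers); zero_grads(hlayers)
        p <- unet_forward(net, bt$x, train = TRUE)
        lg <- combined_loss_grad(p[, , , bt$lab_idx, drop = FALSE], bt$y, lw)
        dp <- array(0, dim(p))
        dp[, , , bt$lab_idx] <- lg$dp
        feat <- grad_reverse(net$tap_bottleneck, dcfg$grl_lambda)
        q <- head_forward(head, feat, train = TRUE)
        dce <- domain_ce_grad(q, bt$domains)
        dfeat <- head_backward(head, dce$dq)
        unet_backward(net, dp,
                      inject_bottleneck = grad_reverse_grad(dfeat, dcfg$grl_lambda))
        opt_step(opt_main, ulayers, lr = lr)
        opt_step(opt_dom, hlayers)
        seg_sum <- seg_sum + lg$loss; seg_n <- seg_n + 1
        dom_sum <- dom_sum + dce$loss; acc_sum <- acc_sum + dce$accuracy
      }
      val_acc <- domain_head_accuracy(net, head, c(val_s, val_t),
                                      tcfg$batch_size)
      logs[[length(logs) + 1]] <- data.frame(
        plane = plane, epoch = epoch, lr = lr,
        seg_loss = seg_sum / seg_n, domain_loss = dom_sum / seg_n,
        domain_accuracy = acc_sum / seg_n, val_domain_accuracy = val_acc)
    }
  }
  list(ensemble = ensemble, heads = heads, log = do.call(rbind, logs))
}

# accuracy of a domain head on a list of samples (eval mode)
domain_head_accuracy <- function(net, head, samples, batch_size = 8) {
  n <- length(samples)
  correct <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    bt <- mixed_batch(samples, list(), idx, integer(0))
    unet_forward(net, bt$x, train = FALSE)
    q <- head_forward(head, net$tap_bottleneck, train = FALSE)
    correct <- correct + sum((q[, 2] > 0.5) == (bt$domains == 1))
  }
  correct / n
}

#' Extract pooled feature vectors with domain labels
#'
#' Runs the (first-plane by default) network over every subject's slices in
#' eval mode and globally average-pools the requested tap, yielding one
#' feature vector per slice — the input for the domain-accuracy probe and
#' for 2D neighbour embeddings.
#'
#' @param ensemble a `triplanar_ensemble`.
#' @param subjects list of `wmhda_subject`.
#' @param tap `"bottleneck"` or `"pre_label_predictor"` (final decoder
#'   output).
#' @param plane plane to use (default: the ensemble's first).
#' @param batch_size forward batch size.
#' @return list with `features` (matrix, rows = slices) and `domains`.
#' @export
extract_features <- function(ensemble, subjects,
                             tap = c("bottleneck", "pre_label_predictor"),
                             plane = NULL, batch_size = 8) {
  tap <- match.arg(tap)
  plane <- plane %||% ensemble$planes[1]
  net <- ensemble$nets[[plane]]
  feats <- list(); doms <- character(0)
  for (s in subjects) {
    pp <- preprocess_subject_plane(s, plane, ensemble$resize_dims[[plane]],
                                   crop_margin = ensemble$crop_margin,
                                   keep = "brain")
    n <- dim(pp$x)[4]
    for (b in seq_len(ceiling(n / batch_size))) {
      idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
      unet_forward(net, pp$x[, , , idx, drop = FALSE], train = FALSE)
      f <- if (tap == "bottleneck") net$tap_bottleneck else net$tap_decoder
      df <- dim(f)
      pooled <- t(matrix(colMeans(matrix(f, df[1] * df[2], df[3] * df[4])),
                         df[3], df[4]))
      feats[[length(feats) + 1]] <- pooled
      doms <- c(doms, rep(s$domain, length(idx)))
    }
  }
  list(features = do.call(rbind, feats), domains = doms)
}
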