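#' Iterative domain unlearning (DU)
#'
#' Instead of a gradient reversal layer, DU alternates three sequential
#' updates per mixed-domain batch: (1) feature extractor + label predictor
#' on the segmentation loss, (2) the domain predictor alone on the domain
#' cross-entropy with features fixed, (3) the feature extractor alone on a
#' beta-weighted confusion loss (cross-entropy of the predicted domain
#' distribution against the uniform distribution) with the domain predictor
#' fixed. The label predictor is the final decoder block's two 3x3
#' convolutions plus the output projection and softmax; the domain predictor
#' attaches at the label predictor's input.
#'
#' @name wmhda-adapt-du
NULL

#' DU configuration
#'
#' @param beta weight of the domain-confusion loss (default 50, chosen in
#'   the source work so that validation domain accuracy lands closest to
#'   50%).
#' @param fc_widths FC widths of the domain head (printed: 468, 96, 32).
#' @param first_fc_input required flattened size after repeated 2x2 pooling;
#'   defaults to `fc_widths[1]`.
#' @param dropout dropout probability.
#' @param lr Adam learning rate for all three DU steps.
#' @param beta_grid candidate beta values for [tune_beta()].
#' @export
du_config <- function(beta = 50, fc_widths = c(468, 96, 32),
                      first_fc_input = NULL, dropout = 0.2, lr = 1e-4,
                      beta_grid = seq(20, 60, by = 10)) {
  stopifnot(beta > 0, length(beta_grid) >= 1, dropout >= 0, dropout < 1,
            length(fc_widths) == 3)
  structure(list(beta = beta, fc_widths = fc_widths,
                 first_fc_input = first_fc_input %||% fc_widths[1],
                 dropout = dropout, lr = lr, beta_grid = beta_grid),
            class = "du_config")
}

#' Build the DU domain-predictor head
#'
#' Repeated 2x2 max-pooling until the flattened dimension equals
#' `first_fc_input`, then FC `fc_widths[1]`, dropout, FC `fc_widths[2]`,
#' dropout, FC `fc_widths[3]`, a 2-way projection and softmax. If no pooling
#' count achieves the required flat size the error lists the achievable
#' sizes.
#'
#' @param input_dims tap dims `(h, w, channels)` at the label-predictor
#'   input.
#' @param config a [du_config()].
#' @param seed weight-init seed.
#' @export
build_du_domain_head <- function(input_dims, config = du_config(), seed = 0) {
  h0 <- input_dims[1]; w0 <- input_dims[2]; ch <- input_dims[3]
  sizes <- c(); hh <- h0; ww <- w0; k <- 0
  pools <- NA
  repeat {
    flat <- hh * ww * ch
    sizes <- c(sizes, flat)
    if (flat == config$first_fc_input) { pools <- k; break }
    if (hh %% 2 != 0 || ww %% 2 != 0 || flat < config$first_fc_input) break
    hh <- hh / 2; ww <- ww / 2; k <- k + 1
  }
  if (is.na(pools))
    stop("cannot pool ", h0, "x", w0, "x", ch, " to a flat size of ",
         config$first_fc_input, "; achievable sizes: ",
         paste(sizes, collapse = ", "))
  rng <- rng_make(seed)
  h <- head_new()
  for (j in seq_len(pools)) head_add(h, "pool", nn_maxpool2())
  head_add(h, "flatten", cache_env())
  head_add(h, "linear", nn_linear(config$first_fc_input, config$fc_widths[1], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "dropout", nn_dropout(config$dropout, rng_make(derive_seed(seed, 1, 61))))
  head_add(h, "linear", nn_linear(config$fc_widths[1], config$fc_widths[2], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "dropout", nn_dropout(config$dropout, rng_make(derive_seed(seed, 2, 61))))
  head_add(h, "linear", nn_linear(config$fc_widths[2], config$fc_widths[3], rng))
  head_add(h, "relu", cache_env())
  head_add(h, "linear", nn_linear(config$fc_widths[3], 2, rng))
  head_add(h, "softmax", cache_env())
  h$n_pools <- pools
  h
}

#' Beta-weighted domain-confusion loss
#'
#' `beta` times the mean cross-entropy between each predicted domain
#' distribution and the uniform distribution: minimal (value `beta * log 2`)
#' exactly when every row is uniform.
#'
#' @param domain_probs row-stochastic matrix `(n, 2)`.
#' @param beta positive weight.
#' @return scalar loss `>= beta * log(2)`.
#' @export
confusion_loss <- function(domain_probs, beta = 50) {
  confusion_loss_grad(domain_probs, beta, want_grad = FALSE)$loss
}

confusion_loss_grad <- function(q, beta, want_grad = TRUE) {
  if (any(abs(rowSums(q) - 1) > 1e-6)) stop("rows are not normalised")
  n <- nrow(q); eps <- 1e-12
  loss <- beta * mean(rowSums(-0.5 * log(pmax(q, eps))))
  out <- list(loss = loss)
  if (want_grad) out$dq <- -beta * 0.5 / (n * pmax(q, eps))
  out
}

# layer-name sets for the DU update steps
du_label_predictor_names <- function(net)
  c(paste0("dec1", c("_conv1", "_bn1", "_conv2", "_bn2")), "out_conv")

du_feature_extractor_layers <- function(net) {
  layers <- unet_layers(net)
  layers[setdiff(names(layers), du_label_predictor_names(net))]
}

#' One DU iteration (three sequential sub-steps) on a mixed batch
#'
#' Step isolation: step 2 touches only the domain head (features are
#' computed in eval mode, so not even batch-norm statistics of the main
#' network move); step 3 touches only the feature extractor (the label
#' predictor's layers are frozen for the step and the head is not stepped).
#'
#' @param net a `planar_unet`.
#' @param head a DU domain head.
#' @param batch list from `mixed_batch()` (fields `x`, `y`, `lab_idx`,
#'   `domains`); must contain both domains.
#' @param config a [du_config()].
#' @param opt_main,opt_head,opt_feat Adam optimisers for steps 1-3.
#' @param lw segmentation [loss_weights()].
#' @return list of the three step losses (`seg`, `domain`, `confusion`) and
#'   the batch domain accuracy.
#' @export
du_iteration <- function(net, head, batch, config, opt_main, opt_head,
                         opt_feat, lw = loss_weights()) {
  if (length(unique(batch$domains)) < 2)
    stop("DU iteration requires a mixed-domain batch")
  if (length(batch$lab_idx) == 0) stop("no labelled samples in batch")
  ulayers <- unet_layers(net)
  hlayers <- head_layers(head)
  feat_layers <- du_feature_extractor_layers(net)
  lp_names <- du_label_predictor_names(net)

  # step 1: segmentation loss -> feature extractor + label predictor
  zero_grads(ulayers)
  p <- unet_forward(net, batch$x, train = TRUE)
  lg <- combined_loss_grad(p[, , , batch$lab_idx, drop = FALSE], batch$y, lw)
  dp <- array(0, dim(p))
  dp[, , , batch$lab_idx] <- lg$dp
  unet_backward(net, dp)
  opt_step(opt_main, ulayers, lr = config$lr)

  # step 2: domain CE -> head only, features fixed (eval-mode forward)
  unet_forward(net, batch$x, train = FALSE)
  feat <- net$tap_label_in
  zero_grads(hlayers)
  q <- head_forward(head, feat, train = TRUE)
  dce <- domain_ce_grad(q, batch$domains)
  head_backward(head, dce$dq)
  opt_step(opt_head, hlayers, lr = config$lr)

  # step 3: confusion loss -> feature extractor only, head fixed
  was_frozen <- vapply(lp_names, function(nm) ulayers[[nm]]$frozen, logical(1))
  for (nm in lp_names) ulayers[[nm]]$frozen <- TRUE
  zero_grads(ulayers)
  unet_forward(net, batch$x, train = TRUE)
  q3 <- head_forward(head, net$tap_label_in, train = FALSE)
  cg <- confusion_loss_grad(q3, config$beta)
  dfeat <- head_backward(head, cg$dq)
  unet_backward(net, dprob = NULL, inject_label_in = dfeat)
  opt_step(opt_feat, feat_layers, lr = config$lr)
  for (j in seq_along(lp_names)) ulayers[[lp_names[j]]]$frozen <- was_frozen[j]

  list(seg = lg$loss, domain = dce$loss, confusion = cg$loss,
       domain_accuracy = dce$accuracy)
}

#' Train a DU-adapted ensemble
#'
#' Runs [du_iteration()] over 50/50 mixed-domain batches for the requested
#' number of epochs; only source lesion labels are read. All DU updates use
#' Adam at `config$lr`.
#'
#' @inheritParams train_dann
#' @param config a [du_config()].
#' @return list with `ensemble`, `heads`, `log` (per epoch: step losses and
#'   validation domain accuracy).
#' @export
train_du <- function(ensemble, source_cohort, target_cohort,
                     config = du_config(), tcfg = train_config(),
                     lw = loss_weights(), epochs = NULL) {
  stopifnot(length(source_cohort) >= 1, length(target_cohort) >= 1)
  epochs <- epochs %||% tcfg$max_epochs
  heads <- list(); logs <- list()
  for (pi in seq_along(ensemble$planes)) {
    plane <- ensemble$planes[pi]
    net <- ensemble$nets[[plane]]
    seed_p <- derive_seed(tcfg$seed, pi, tag = 71)
    pools <- adversarial_samples(source_cohort, target_cohort, plane,
                                 ensemble$resize_dims[[plane]],
                                 ensemble$crop_margin, integer(0))
    rngv <- rng_make(derive_seed(seed_p, 1, tag = 72))
    nval <- function(pool) max(1, floor(0.1 * length(pool)))
    vs <- rng_sample(rngv, length(pools$source))[seq_len(nval(pools$source))]
    vt <- rng_sample(rngv, length(pools$target))[seq_len(nval(pools$target))]
    val <- c(pools$source[vs], pools$target[vt])
    src <- pools$source[-vs]; tgt <- pools$target[-vt]

    d <- net$config$depth
    rd <- ensemble$resize_dims[[plane]]
    tap_dims <- c(rd, 2 * net$config$channels[1])
    head <- build_du_domain_head(tap_dims, config,
                                 seed = derive_seed(seed_p, 2, 73))
    heads[[plane]] <- head
    opt_main <- opt_adam(eps = tcfg$adam_eps)
    opt_head <- opt_adam(eps = tcfg$adam_eps)
    opt_feat <- opt_adam(eps = tcfg$adam_eps)
    rngb <- rng_make(derive_seed(seed_p, 3, tag = 74))
    half <- max(1, floor(tcfg$batch_size / 2))
    steps <- ceiling(max(length(src), length(tgt)) / half)
    for (epoch in seq_len(epochs) - 1) {
      ord_s <- rng_sample(rngb, length(src), size = steps * half, replace = TRUE)
      ord_t <- rng_sample(rngb, length(tgt), size = steps * half, replace = TRUE)
      sums <- c(seg = 0, domain = 0, confusion = 0, domain_accuracy = 0)
      for (st in seq_len(steps)) {
        take <- ((st - 1) * half + 1):(st * half)
        bt <- mixed_batch(src, tgt, ord_s[take], ord_t[take])
        res <- du_iteration(net, head, bt, config, opt_main, opt_head,
                            opt_feat, lw)
        sums <- sums + unlist(res)
      }
      val_acc <- du_head_accuracy(net, head, val, tcfg$batch_size)
      logs[[length(logs) + 1]] <- data.frame(
        plane = plane, epoch = epoch, t(sums / steps),
        val_domain_accuracy = val_acc)
    }
  }
  list(ensemble = ensemble, heads = heads, log = do.call(rbind, logs))
}

du_head_accuracy <- function(net, head, samples, batch_size = 8) {
  n <- length(samples)
  correct <- 0
  for (b in seq_len(ceiling(n / batch_size))) {
    idx <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    bt <- mixed_batch(samples, list(), idx, integer(0))
    unet_forward(net, bt$x, train = FALSE)
    q <- head_forward(head, net$tap_label_in, train = FALSE)
    correct <- correct + sum((q[, 2] > 0.5) == (bt$domains == 1))
  }
  correct / n
}

#' Select beta from validation domain accuracies
#'
#' Returns the candidate whose accuracy is closest to 0.5 (maximal domain
#' confusion); ties break towards the smaller beta.
#'
#' @param grid numeric candidate betas.
#' @param accuracies validation domain accuracy per candidate.
#' @return the selected beta.
#' @export
tune_beta <- function(grid, accuracies) {
  if (length(grid) == 0) stop("empty beta grid")
  if (length(grid) != length(accuracies))
    stop("need one accuracy per candidate")
  ord <- order(abs(accuracies - 0.5), grid)
  grid[ord[1]]
}
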