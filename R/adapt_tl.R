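#' Layer-wise transfer learning (fine-tuning with frozen prefix)
#'
#' Adapts a source-trained ensemble to the target domain by freezing all but
#' the last `i` layer blocks (numbered from the decoder end) and fine-tuning
#' on labelled target subjects with a reduced learning-rate schedule
#' (1e-4 decaying by 10x every 2 epochs to a floor of 1e-6). Frozen blocks
#' keep their batch-norm running statistics fixed as well: a frozen layer
#' must not adapt through any channel.
#'
#' @name wmhda-adapt-tl
NULL

#' Partition a planar network's parameters into layer blocks
#'
#' Blocks are numbered from the decoder end: 1 = output projection (+
#' softmax), 2 = decoder (all upsample-conv and decoder conv blocks),
#' 3 = bottleneck, 3+j = encoder level `depth - j`. For the default depth-3
#' network this gives L = 5 with block 3 the 512-channel bottleneck ("3
#' layers from the end" = end of the encoder). The figure fixing the exact
#' composition is a declared convention here, so the map is derived from the
#' architecture rather than hard-coded.
#'
#' @param net a `planar_unet`.
#' @return object of class `layer_index_map`: list with `blocks` (list of
#'   character vectors of layer names per block), `n_blocks`, `param_counts`.
#' @export
layer_blocks <- function(net) {
  if (!inherits(net, "planar_unet")) stop("unknown architecture")
  d <- net$config$depth
  layers <- unet_layers(net)
  block_names <- list()
  block_names[[1]] <- "out_conv"
  dec_names <- unlist(lapply(seq_len(d - 1), function(l)
    c(paste0("upconv", l),
      paste0("dec", l, c("_conv1", "_bn1", "_conv2", "_bn2")))))
  block_names[[2]] <- dec_names
  block_names[[3]] <- paste0("bott", c("_conv1", "_bn1", "_conv2", "_bn2"))
  for (j in seq_len(d - 1))
    block_names[[3 + j]] <- paste0("enc", d - j, c("_conv1", "_bn1", "_conv2", "_bn2"))
  counts <- vapply(block_names, function(nms)
    sum(vapply(nms, function(nm) {
      L <- layers[[nm]]
      sum(vapply(L$param_names, function(p) length(L[[p]]), numeric(1)))
    }, numeric(1))), numeric(1))
  structure(list(blocks = block_names, n_blocks = length(block_names),
                 param_counts = counts),
            class = "layer_index_map")
}

#' Freeze all but the last `i` blocks of every planar network
#'
#' Blocks `i+1 .. L` (towards the input end) are marked non-trainable; an
#' optimiser step then changes no frozen parameter and frozen batch-norm
#' layers keep using their running statistics.
#'
#' @param ensemble a `triplanar_ensemble` (modified in place and returned).
#' @param i number of blocks to fine-tune, `1 <= i <= L`.
#' @export
freeze_for_finetune <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "triplanar_ensemble"))
  for (net in ensemble$nets) {
    map <- layer_blocks(net)
    if (i < 1 || i > map$n_blocks)
      stop("i must be in 1..", map$n_blocks)
    layers <- unet_layers(net)
    for (b in seq_len(map$n_blocks)) {
      for (nm in map$blocks[[b]]) layers[[nm]]$frozen <- (b > i)
    }
  }
  invisible(ensemble)
}

unfreeze_all <- function(ensemble) {
  for (net in ensemble$nets)
    for (L in unet_layers(net)) L$frozen <- FALSE
  invisible(ensemble)
}

# parameters (and BN stats) of the given blocks, for freezing contracts
block_parameters <- function(net, blocks) {
  map <- layer_blocks(net)
  layers <- unet_layers(net)
  nms <- unlist(map$blocks[blocks])
  layers_param_copy(layers[nms])
}

#' Fine-tune a source-trained ensemble on target subjects
#'
#' @param source_ensemble trained `triplanar_ensemble`; left untouched (a
#'   deep copy is fine-tuned).
#' @param target_cohort list of labelled target `wmhda_subject`.
#' @param i layer blocks to fine-tune (from the decoder end).
#' @param n_subjects number of target subjects used (seeded subset).
#' @param seed run seed.
#' @param config training configuration; defaults to the reduced TL schedule
#'   (`lr_init` 1e-4, floor 1e-6) with the caller's epoch budget.
#' @param augment augmentation config (same policy as baseline training).
#' @param lw loss weights.
#' @return list with `ensemble` (adapted copy) and `log`.
#' @export
finetune <- function(source_ensemble, target_cohort, i, n_subjects,
                     seed = 0, config = NULL, augment = augment_config(),
                     lw = loss_weights()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (n_subjects > length(target_cohort))
    stop("n_subjects exceeds cohort size")
  if (is.null(config))
    config <- train_config(lr_init = 1e-4, lr_floor = 1e-6, seed = seed)
  rng <- rng_make(derive_seed(seed, 5, tag = 31))
  pick <- rng_sample(rng, length(target_cohort))[seq_len(n_subjects)]
  ens <- clone_ensemble(source_ensemble)
  freeze_for_finetune(ens, i)
  res <- train_model(ens, target_cohort[pick], config, augment, lw)
  unfreeze_all(res$ensemble)
  res
}

#' Subjects-by-layers fine-tuning sweep
#'
#' For every combination of target training-subject count and
#' layers-to-tune, fine-tunes the source model and records the mean test
#' metrics; emits one matrix per metric (rows = subject counts, cols =
#' layer counts).
#'
#' @param source_ensemble trained ensemble.
#' @param target_train,target_test labelled target cohorts (disjoint).
#' @param subject_counts,layer_counts integer vectors spanning the grid.
#' @param seed run seed.
#' @param config,augment,lw as in [finetune()].
#' @param threshold binarisation threshold for evaluation.
#' @return named list of `|subject_counts| x |layer_counts|` matrices, one
#'   per metric column of [evaluate_subject()].
#' @export
tl_sweep <- function(source_ensemble, target_train, target_test,
                     subject_counts, layer_counts, seed = 0, config = NULL,
                     augment = augment_config(), lw = loss_weights(),
                     threshold = 0.5) {
  if (length(subject_counts) == 0 || length(layer_counts) == 0)
    stop("empty sweep grid")
  if (max(subject_counts) > length(target_train))
    stop("subject_counts exceed available subjects")
  metrics <- c("si", "voxel_tpr", "voxel_fpr", "cluster_tpr",
               "cluster_precision", "cluster_f1", "lavd")
  grids <- lapply(metrics, function(m)
    matrix(NA_real_, length(subject_counts), length(layer_counts),
           dimnames = list(subject_counts, layer_counts)))
  names(grids) <- metrics
  for (si in seq_along(subject_counts)) for (li in seq_along(layer_counts)) {
    ft <- finetune(source_ensemble, target_train, i = layer_counts[li],
                   n_subjects = subject_counts[si],
                   seed = derive_seed(seed, si * 100 + li, tag = 32),
                   config = config, augment = augment, lw = lw)
    ev <- evaluate_cohort(ft$ensemble, target_test, threshold = threshold)
    for (m in metrics)
      grids[[m]][si, li] <- mean(ev[[m]], na.rm = TRUE)
  }
  grids
}

#' Evaluate an ensemble on a cohort
#'
#' Predicts, binarises and scores every subject.
#'
#' @param ensemble a `triplanar_ensemble`.
#' @param cohort list of `wmhda_subject` with reference masks.
#' @param threshold binarisation threshold.
#' @return data.frame with one row per subject (metrics + `subject_id`).
#' @export
evaluate_cohort <- function(ensemble, cohort, threshold = 0.5) {
  rows <- lapply(cohort, function(s) {
    prob <- predict_volume(ensemble, s)
    m <- evaluate_subject(binarize(prob, threshold), s$lesion_mask,
                          voxel_dims = s$voxel_dims,
                          brain_mask = s$brain_mask)
    cbind(data.frame(subject_id = s$subject_id), m)
  })
  do.call(rbind, rows)
}
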