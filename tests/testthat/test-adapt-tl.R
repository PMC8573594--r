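test_that("layer blocks partition all parameters, bottleneck is block 3", {
  net <- build_planar_unet(tiny_unet_config(), seed = 1)
  map <- layer_blocks(net)
  expect_equal(map$n_blocks, 5)   # depth 3 -> L = 5
  expect_equal(sum(map$param_counts), unet_n_parameters(net))
  # every parameter-bearing layer appears in exactly one block
  all_names <- unlist(map$blocks)
  expect_identical(sort(all_names), sort(names(wmhda:::unet_layers(net))))
  expect_false(anyDuplicated(all_names) > 0)
  # block 3 holds the bottleneck convolutions (the widest level)
  expect_true(all(grepl("^bott", map$blocks[[3]])))
  bott_w <- net$bott$conv2$cout
  expect_equal(bott_w, tiny_unet_config()$channels[3])
})

test_that("freezing is airtight: frozen blocks are bit-identical after steps", {
  ens <- tiny_ensemble(seed = 2)
  cohort <- tiny_cohort(2)
  freeze_for_finetune(ens, i = 3)
  net <- ens$nets[[1]]
  before_45 <- wmhda:::block_parameters(net, 4:5)
  before_all <- wmhda:::block_parameters(net, 1:5)
  pp <- preprocess_subject_plane(cohort[[1]], "axial", c(24, 24))
  xb <- pp$x[, , , 1:4]; yb <- pp$y[, , 1:4]
  opt <- wmhda:::opt_adam()
  for (k in 1:3) wmhda:::seg_step(net, xb, yb, opt, loss_weights(), 1e-2)
  after_45 <- wmhda:::block_parameters(net, 4:5)
  expect_identical(before_45, after_45)           # frozen prefix untouched
  after_all <- wmhda:::block_parameters(net, 1:5)
  expect_false(identical(before_all, after_all))  # tuned blocks moved
  # i = 1: only the output block changes
  ens1 <- tiny_ensemble(seed = 2)
  freeze_for_finetune(ens1, i = 1)
  net1 <- ens1$nets[[1]]
  b_rest <- wmhda:::block_parameters(net1, 2:5)
  b_out <- wmhda:::block_parameters(net1, 1)
  opt1 <- wmhda:::opt_adam()
  wmhda:::seg_step(net1, xb, yb, opt1, loss_weights(), 1e-2)
  expect_identical(wmhda:::block_parameters(net1, 2:5), b_rest)
  expect_false(identical(wmhda:::block_parameters(net1, 1), b_out))
  # i = L: everything trainable
  ensL <- tiny_ensemble(seed = 2)
  freeze_for_finetune(ensL, i = 5)
  expect_true(all(!vapply(wmhda:::unet_layers(ensL$nets[[1]]),
                          function(L) L$frozen, logical(1))))
  expect_error(freeze_for_finetune(ens, i = 0), "1..5")
  expect_error(freeze_for_finetune(ens, i = 6), "1..5")
})

test_that("finetune trains only the unfrozen suffix and keeps frozen bytes", {
  ens <- tiny_ensemble(seed = 3)
  cohort <- tiny_cohort(3)
  # short source-side warm start so the network is not at init
  train_model(ens, cohort, train_config(pretrain_epochs = 0, patience = 2,
                                        max_epochs = 1, val_fraction = 0.34,
                                        seed = 1), augment = NULL)
  frozen_before <- wmhda:::block_parameters(ens$nets[[1]], 4:5)
  ft <- finetune(ens, cohort, i = 3, n_subjects = 2, seed = 4,
                 config = train_config(lr_init = 1e-3, lr_floor = 1e-5,
                                       pretrain_epochs = 0, patience = 2,
                                       max_epochs = 2, val_fraction = 0.5,
                                       seed = 4),
                 augment = NULL)
  # the source ensemble itself is untouched (deep copy semantics)
  expect_identical(wmhda:::block_parameters(ens$nets[[1]], 4:5), frozen_before)
  # frozen blocks of the fine-tuned copy are byte-identical to the source
  expect_identical(wmhda:::block_parameters(ft$ensemble$nets[[1]], 4:5),
                   frozen_before)
  expect_error(finetune(ens, cohort, i = 3, n_subjects = 0), ">= 1")
  expect_error(finetune(ens, cohort, i = 3, n_subjects = 10), "exceeds")
})

test_that("the sweep emits one grid cell per (subjects, layers) pair", {
  ens <- tiny_ensemble(seed = 5)
  cohort <- tiny_cohort(3)
  train_model(ens, cohort, train_config(pretrain_epochs = 0, patience = 1,
                                        max_epochs = 1, val_fraction = 0.34,
                                        seed = 1), augment = NULL)
  grids <- tl_sweep(ens, cohort[1:2], cohort[3],
                    subject_counts = c(1, 2), layer_counts = c(1, 5),
                    seed = 1,
                    config = train_config(pretrain_epochs = 0, patience = 1,
                                          max_epochs = 1, val_fraction = 0.5,
                                          seed = 1),
                    augment = NULL)
  expect_named(grids, c("si", "voxel_tpr", "voxel_fpr", "cluster_tpr",
                        "cluster_precision", "cluster_f1", "lavd"))
  expect_equal(dim(grids$si), c(2, 2))
  expect_true(all(is.finite(grids$si)))
  expect_error(tl_sweep(ens, cohort[1:2], cohort[3], integer(0), 1), "empty")
})
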