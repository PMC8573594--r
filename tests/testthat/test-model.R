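test_that("network construction follows the config", {
  cfg <- tiny_unet_config()
  net <- build_planar_unet(cfg, seed = 3)
  # depth 3 -> exactly 2 pooling stages in the encoder
  expect_length(net$pools, 2)
  expect_equal(cfg$channels, c(4, 8, 16))
  expect_error(planar_unet_config(depth = 1), "depth")
  # seeded determinism: identical builds
  net2 <- build_planar_unet(cfg, seed = 3)
  expect_identical(unet_n_parameters(net), unet_n_parameters(net2))
  for (nm in names(unet_layers(net)))
    expect_identical(unet_layers(net)[[nm]]$W %||% unet_layers(net)[[nm]]$gamma,
                     unet_layers(net2)[[nm]]$W %||% unet_layers(net2)[[nm]]$gamma)
})

test_that("forward pass yields a per-pixel softmax of the right shape", {
  net <- build_planar_unet(tiny_unet_config(), seed = 1)
  x <- array(rnorm(16 * 20 * 2 * 3), c(16, 20, 2, 3))
  p <- unet_forward(net, x)
  expect_equal(dim(p), c(16, 20, 2, 3))
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(p[, , 1, ] + p[, , 2, ], array(1, c(16, 20, 3)),
               tolerance = 1e-12)
  expect_error(unet_forward(net, array(0, c(15, 20, 2, 1))), "divisible")
})

test_that("weighted cross-entropy matches a hand-computed 2x2 example", {
  # 2x2 image, probabilities chosen by hand
  p2 <- c(0.9, 0.2, 0.6, 0.5)   # WMH-channel probability per pixel
  y <- c(1, 0, 1, 0)
  p <- array(0, c(2, 2, 2, 1))
  p[, , 2, 1] <- p2; p[, , 1, 1] <- 1 - p2
  ya <- array(y, c(2, 2, 1))
  ref <- mean(-log(c(0.9, 0.8, 0.6, 0.5)))   # independent formula
  expect_equal(weighted_cross_entropy(p, ya, array(1, c(2, 2, 1))), ref,
               tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(p, ya), ref, tolerance = 1e-12)
  # linearity in weights
  expect_equal(weighted_cross_entropy(p, ya, array(2, c(2, 2, 1))), 2 * ref,
               tolerance = 1e-12)
  # perfect confident prediction -> ~0
  ph <- array(0, c(2, 2, 2, 1)); ph[, , 2, 1] <- y; ph[, , 1, 1] <- 1 - y
  expect_lt(weighted_cross_entropy(ph, ya), 1e-6)
  expect_error(weighted_cross_entropy(p, array(0, c(3, 3, 1))), "shape")
})

test_that("soft Dice follows its closed form", {
  # 4-pixel example: p = (1,1,0,0), y = (1,0,0,0) -> 1 - 2/3 = 1/3
  p <- array(0, c(2, 2, 2, 1))
  p[, , 2, 1] <- c(1, 1, 0, 0); p[, , 1, 1] <- 1 - p[, , 2, 1]
  y <- array(c(1, 0, 0, 0), c(2, 2, 1))
  expect_equal(soft_dice_loss(p, y, eps = 1e-12), 1 / 3, tolerance = 1e-9)
  # perfect one-hot -> ~0; all-zero prediction vs nonempty mask -> ~1
  ph <- array(0, c(2, 2, 2, 1)); ph[, , 2, 1] <- c(1, 0, 0, 0)
  ph[, , 1, 1] <- 1 - ph[, , 2, 1]
  expect_lt(soft_dice_loss(ph, y), 1e-6)
  p0 <- array(0, c(2, 2, 2, 1)); p0[, , 1, 1] <- 1
  expect_gt(soft_dice_loss(p0, y), 0.999)
})

test_that("combined loss is the weighted sum of its parts", {
  p <- array(stats::runif(2 * 2 * 1), c(2, 2, 2, 1))
  p[, , 1, ] <- 1 - p[, , 2, ]
  y <- array(c(1, 0, 0, 1), c(2, 2, 1))
  lw_ce <- loss_weights(lambda_ce = 1, lambda_dice = 0,
                        voxel_weight_mode = "none")
  lw_di <- loss_weights(lambda_ce = 0, lambda_dice = 1)
  lw_both <- loss_weights(voxel_weight_mode = "none")
  expect_equal(combined_loss(p, y, lw_ce), weighted_cross_entropy(p, y))
  expect_equal(combined_loss(p, y, lw_di), soft_dice_loss(p, y))
  expect_equal(combined_loss(p, y, lw_both),
               weighted_cross_entropy(p, y) + soft_dice_loss(p, y),
               tolerance = 1e-12)
  expect_error(loss_weights(-1, 1), ">= 0")
  expect_error(loss_weights(0, 0), "zero")
})

test_that("binarize thresholds correctly and monotonically", {
  v <- array(0.6, c(3, 3, 3))
  expect_true(all(binarize(v, 0.5) == 1))
  expect_true(all(binarize(array(0.4, c(3, 3, 3)), 0.5) == 0))
  prob <- array(stats::runif(4^3), c(4, 4, 4))
  m1 <- binarize(prob, 0.3); m2 <- binarize(prob, 0.7)
  expect_true(all(m2 <= m1))   # raising the threshold never adds voxels
  expect_error(binarize(prob, 0), NULL)
})

test_that("predict_volume averages planes and stays in [0,1]", {
  ens <- tiny_ensemble(planes = c("axial", "sagittal", "coronal"))
  s <- tiny_cohort(1)[[1]]
  prob <- predict_volume(ens, s)
  expect_equal(dim(prob), dim(s$flair))
  expect_true(all(prob >= 0 & prob <= 1))
  # constant-output networks: force logits to constants via zeroed weights
  q <- 0.73
  for (net in ens$nets) {
    oc <- net$out_conv
    oc$W[] <- 0
    oc$b <- c(log(1 - q), log(q))
  }
  prob_q <- predict_volume(ens, s)
  box <- crop_fov(s$flair, s$brain_mask, 2)$crop_box
  inner <- prob_q[box["lo", 1]:box["hi", 1], box["lo", 2]:box["hi", 2],
                  box["lo", 3]:box["hi", 3]]
  expect_true(all(abs(inner - q) < 1e-6))
  # permutation invariance over planes
  ens2 <- ens; ens2$planes <- rev(ens$planes)
  ens2$nets <- ens$nets[rev(ens$planes)]
  expect_equal(predict_volume(ens2, s), prob_q, tolerance = 1e-12)
})

test_that("gradients are sane: one repeated batch is driven to near zero loss", {
  cohort <- tiny_cohort(2)
  pp <- preprocess_subject_plane(cohort[[1]], "axial", c(24, 24))
  idx <- order(-apply(pp$y, 3, sum))[1:6]   # lesion-rich slices
  xb <- pp$x[, , , idx]; yb <- pp$y[, , idx]
  net <- build_planar_unet(tiny_unet_config(base = 8, bott = 32), seed = 2)
  opt <- wmhda:::opt_adam()
  lw <- loss_weights()
  losses <- vapply(1:200, function(i)
    wmhda:::seg_step(net, xb, yb, opt, lw, lr = 5e-3), numeric(1))
  expect_lt(losses[200], 0.05)
  # decreasing in trend
  expect_lt(mean(losses[151:200]), mean(losses[1:50]))
})
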