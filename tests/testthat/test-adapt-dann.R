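test_that("gradient reversal: identity forward, -lambda-scaled backward", {
  x <- array(rnorm(24), c(2, 3, 4))
  expect_identical(grad_reverse(x, 1), x)
  expect_identical(grad_reverse(x, 0.3), x)
  g <- c(2, -4)
  expect_equal(grad_reverse_grad(g, 1), -g)
  expect_equal(grad_reverse_grad(g, 0.5), c(-1, 2))
  expect_equal(grad_reverse_grad(g, 0), c(0, 0))
})

test_that("reversal correctness: main path receives the negated domain gradient", {
  # finite-difference check through the real wiring: loss = domain CE of the
  # head on the bottleneck tap; the feature extractor must receive exactly
  # -lambda times d(CE)/d(theta) under injection.
  net <- build_planar_unet(tiny_unet_config(), seed = 7)
  head <- build_domain_head(c(6, 6, 16),
                            dann_config(proj_channels = c(8, 4),
                                        fc_widths = c(16, 8, 4), dropout = 0),
                            seed = 1)
  # fixed stream: keeps the finite-difference probe off ReLU/max-pool kinks
  x <- array(rng_norm(rng_make(77), 24 * 24 * 2 * 4), c(24, 24, 2, 4))
  dom <- c(0L, 1L, 0L, 1L)
  lambda <- 0.7
  domain_loss <- function() {
    unet_forward(net, x, train = TRUE)
    q <- head_forward(head, net$tap_bottleneck, train = FALSE)
    wmhda:::domain_ce_grad(q, dom, want_grad = TRUE)
  }
  layers <- wmhda:::unet_layers(net)
  L <- layers[["enc1_conv1"]]
  wmhda:::zero_grads(layers)
  dce <- domain_loss()
  dfeat <- head_backward(head, dce$dq)
  unet_backward(net, dprob = NULL,
                inject_bottleneck = grad_reverse_grad(dfeat, lambda))
  g_analytic <- L$gW[5]
  eps <- 1e-5; orig <- L$W[5]
  L$W[5] <- orig + eps; lp <- domain_loss()$loss
  L$W[5] <- orig - eps; lm <- domain_loss()$loss
  L$W[5] <- orig
  g_num <- (lp - lm) / (2 * eps)
  expect_equal(g_analytic, -lambda * g_num, tolerance = 1e-6)
})

test_that("the domain head has the printed architecture and softmax output", {
  cfg <- dann_config()
  expect_equal(cfg$fc_widths, c(1024, 512, 32))
  expect_equal(cfg$proj_channels, c(128, 64))
  expect_equal(cfg$dropout, 0.2)
  expect_equal(cfg$domain_momentum, 0.9)
  # small instantiation: widths taken from the config
  head <- build_domain_head(c(8, 8, 16),
                            dann_config(proj_channels = c(8, 4),
                                        fc_widths = c(32, 16, 8)), seed = 2)
  x <- array(rnorm(8 * 8 * 16 * 5), c(8, 8, 16, 5))
  q <- head_forward(head, x, train = FALSE)
  expect_equal(dim(q), c(5, 2))
  expect_equal(rowSums(q), rep(1, 5), tolerance = 1e-12)
  q2 <- head_forward(head, x, train = FALSE)
  expect_identical(q, q2)   # no dropout at eval
  # first FC input follows the pooled/projected spatial size
  lin <- wmhda:::head_layers(head)[[3]]
  expect_equal(dim(lin$W), c(4 * 4 * 4, 32))
  expect_error(build_domain_head(c(7, 8, 16), dann_config()), "incompatible")
})

test_that("select_semi_subset matches the printed 25% rule", {
  subjects <- as.list(1:16)
  idx <- select_semi_subset(subjects, 0.25, seed = 3)
  expect_length(idx, 4)     # 25% of 16 = 4 subjects
  expect_true(all(idx %in% 1:16))
  expect_identical(select_semi_subset(subjects, 0.25, seed = 3), idx)
  expect_length(select_semi_subset(subjects, 0), 0)
  expect_length(select_semi_subset(as.list(1:10), 0.25, seed = 1), 2) # floor
  expect_error(select_semi_subset(subjects, 1.2), "fraction")
})

test_that("unsupervised DANN runs without target lesion labels existing", {
  cohort_src <- tiny_cohort(3)
  cohort_tgt <- lapply(tiny_cohort(3, seed = 21), function(s) {
    s$lesion_mask <- NULL   # labels do not exist -> cannot be read
    s
  })
  ens <- tiny_ensemble(seed = 8)
  res <- train_dann(ens, cohort_src, cohort_tgt,
                    dcfg = dann_config(semi_fraction = 0,
                                       proj_channels = c(8, 4),
                                       fc_widths = c(16, 8, 4)),
                    tcfg = train_config(pretrain_epochs = 0, patience = 1,
                                        max_epochs = 2, seed = 1),
                    epochs = 1)
  expect_true(all(c("seg_loss", "domain_loss", "domain_accuracy",
                    "val_domain_accuracy") %in% colnames(res$log)))
  expect_true(is.finite(res$log$seg_loss[1]))
})

test_that("domain head learns separable domains from a fixed slice pool", {
  # a finite pool of feature samples that recur across epochs, as in real
  # adaptation training (slices of a fixed cohort)
  rng <- rng_make(2)
  n_pool <- 24; n_test <- 16
  mk <- function(n, seed_off) {
    dom <- rep(c(0L, 1L), length.out = n)
    f <- array(abs(rng_norm(rng, 6 * 6 * 16 * n)), c(6, 6, 16, n))
    f[, , , dom == 1] <- f[, , , dom == 1] * 2   # separable feature scale
    list(f = f, dom = dom)
  }
  pool <- mk(n_pool); test <- mk(n_test)
  head <- build_domain_head(c(6, 6, 16),
                            dann_config(proj_channels = c(8, 8),
                                        fc_widths = c(32, 16, 8), dropout = 0),
                            seed = 3)
  hl <- wmhda:::head_layers(head)
  opt <- wmhda:::opt_sgdm(lr = 1e-3, momentum = 0.9)
  for (epoch in 1:60) {
    for (b in 1:3) {
      idx <- ((b - 1) * 8 + 1):(b * 8)
      wmhda:::zero_grads(hl)
      q <- head_forward(head, pool$f[, , , idx, drop = FALSE], train = TRUE)
      dce <- wmhda:::domain_ce_grad(q, pool$dom[idx])
      head_backward(head, dce$dq)
      wmhda:::opt_step(opt, hl)
    }
  }
  # head sanity: >90% domain accuracy on its training pool (what the
  # adaptation loops monitor); a 576-dim head on 24 samples is expected to
  # overfit, so held-out accuracy is not asserted here
  q <- head_forward(head, pool$f, train = FALSE)
  expect_gt(mean((q[, 2] > 0.5) == (pool$dom == 1)), 0.9)
  q_te <- head_forward(head, test$f, train = FALSE)
  expect_gt(mean((q_te[, 2] > 0.5) == (test$dom == 1)), 0.5)
})

test_that("extract_features pools one row per slice, deterministically", {
  ens <- tiny_ensemble(seed = 10)
  cohort <- tiny_cohort(2)
  fx <- extract_features(ens, cohort, tap = "bottleneck")
  n_slices <- sum(vapply(cohort, function(s) {
    pp <- preprocess_subject_plane(s, "axial", c(24, 24), keep = "brain")
    dim(pp$x)[4]
  }, numeric(1)))
  expect_equal(nrow(fx$features), n_slices)
  expect_equal(ncol(fx$features), 16)   # bottleneck channels
  expect_length(fx$domains, n_slices)
  fx2 <- extract_features(ens, cohort, tap = "bottleneck")
  expect_identical(fx, fx2)
  fxd <- extract_features(ens, cohort, tap = "pre_label_predictor")
  expect_equal(ncol(fxd$features), 4)   # decoder output channels
  expect_error(extract_features(ens, cohort, tap = "nonsense"), "arg")
})
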