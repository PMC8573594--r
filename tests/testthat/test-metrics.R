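test_that("dice_si matches its definition and degenerate conventions", {
  m <- array(0, c(4, 4, 4)); m[1:2, 1, 1] <- 1
  expect_equal(dice_si(m, m), 1)
  m2 <- array(0, c(4, 4, 4)); m2[4, 4, 4] <- 1
  expect_equal(dice_si(m, m2), 0)
  # |true| = 4, |pred| = 8, overlap = 3 -> 0.5
  truth <- array(0, c(4, 4, 4)); truth[1:4, 1, 1] <- 1
  pred <- array(0, c(4, 4, 4)); pred[2:4, 1, 1] <- 1; pred[1:4, 2, 1] <- 1
  pred[1, 3, 1] <- 1
  expect_equal(sum(truth), 4); expect_equal(sum(pred), 8)
  expect_equal(sum(pred * truth), 3)
  expect_equal(dice_si(pred, truth), 0.5)
  expect_equal(dice_si(array(0, c(2, 2, 2)), array(0, c(2, 2, 2))), 1)
  expect_error(dice_si(m, array(0, c(3, 3, 3))), "shape")
  expect_error(dice_si(array(0.5, c(2, 2, 2)), m2), "binary")
})

test_that("voxel_rates handles counts, brain masks and empty truth", {
  truth <- array(0, c(10, 10, 1)); truth[1:4, 1, 1] <- 1
  pred <- array(0, c(10, 10, 1)); pred[1:3, 1, 1] <- 1; pred[6:7, 1, 1] <- 1
  r <- voxel_rates(pred, truth)
  expect_equal(r$tpr, 0.75)
  expect_equal(r$fpr, 2 / 96)
  perfect <- voxel_rates(truth, truth)
  expect_equal(perfect$tpr, 1); expect_equal(perfect$fpr, 0)
  allpos <- voxel_rates(array(1, dim(truth)), truth)
  expect_equal(allpos$tpr, 1); expect_equal(allpos$fpr, 1)
  # empty truth -> flagged NA, not zero
  expect_true(is.na(voxel_rates(pred, array(0, dim(truth)))$tpr))
  # brain mask restricts the denominator
  bm <- array(0, dim(truth)); bm[1:8, 1, 1] <- 1
  rb <- voxel_rates(pred, truth, brain_mask = bm)
  expect_equal(rb$fpr, 2 / 4)
})

test_that("26-connectivity clustering follows the neighbourhood definition", {
  m <- array(0, c(5, 5, 5)); m[2, 2, 2] <- 1
  expect_equal(label_clusters_26(m)$n_clusters, 1)
  # corner contact joins
  m[3, 3, 3] <- 1
  expect_equal(label_clusters_26(m)$n_clusters, 1)
  # a 2-voxel gap separates
  m2 <- array(0, c(7, 5, 5)); m2[1, 1, 1] <- 1; m2[4, 1, 1] <- 1
  expect_equal(label_clusters_26(m2)$n_clusters, 2)
  expect_error(label_clusters_26(matrix(0, 3, 3)), "3D")
})

test_that("cluster metrics follow the any-overlap rule and F1 formula", {
  d <- c(12, 12, 3)
  truth <- array(0, d)
  truth[1:2, 1:2, 1] <- 1; truth[6:7, 6:7, 1] <- 1; truth[10:11, 10:11, 3] <- 1
  pred <- array(0, d)
  pred[2, 2, 1] <- 1                 # overlaps true cluster 1
  pred[6, 6, 1] <- 1                 # overlaps true cluster 2
  pred[1, 12, 2] <- 1                # false positive cluster
  pred[12, 1, 2] <- 1                # false positive cluster
  cm <- cluster_metrics(pred, truth)
  expect_equal(cm$n_true_clusters, 3)
  expect_equal(cm$n_pred_clusters, 4)
  expect_equal(cm$cluster_tpr, 2 / 3)
  expect_equal(cm$cluster_precision, 1 / 2)
  expect_equal(cm$cluster_f1, 4 / 7)
  perfect <- cluster_metrics(truth, truth)
  expect_equal(unlist(perfect[1:3]), c(cluster_tpr = 1, cluster_precision = 1,
                                       cluster_f1 = 1))
  # empty prediction: TPR 0, precision degenerates to 0, F1 0
  empty <- cluster_metrics(array(0, d), truth)
  expect_equal(empty$cluster_tpr, 0)
  expect_equal(empty$cluster_precision, 0)
  expect_equal(empty$cluster_f1, 0)
})

test_that("lavd is the absolute natural-log volume ratio", {
  expect_equal(lavd(10, 10), 0)
  expect_equal(lavd(20, 10), log(2))
  expect_equal(lavd(3, 17), lavd(17, 3))
  expect_error(lavd(0, 5), "degenerate")
})

test_that("evaluate_subject aggregates and voxel dims scale only volumes", {
  truth <- random_mask(c(8, 8, 8), 0.1, seed = 3)
  rep1 <- evaluate_subject(truth, truth)
  expect_equal(rep1$si, 1); expect_equal(rep1$lavd, 0)
  expect_equal(rep1$cluster_f1, 1); expect_equal(rep1$voxel_fpr, 0)
  pred <- random_mask(c(8, 8, 8), 0.12, seed = 4)
  iso <- evaluate_subject(pred, truth, voxel_dims = c(1, 1, 1))
  aniso <- evaluate_subject(pred, truth, voxel_dims = c(1, 1, 3))
  expect_equal(iso$si, aniso$si)          # SI dimensionless
  expect_equal(iso$lavd, aniso$lavd)      # ratio cancels isotropic scaling
})

test_that("all metrics match brute-force oracles on random 16^3 mask pairs", {
  for (i in 1:20) {
    pred <- random_mask(c(16, 16, 16), 0.02 + 0.003 * i, seed = 100 + i)
    truth <- random_mask(c(16, 16, 16), 0.02 + 0.002 * i, seed = 200 + i)
    expect_equal(dice_si(pred, truth), oracle_dice(pred, truth),
                 tolerance = 1e-12)
    r <- voxel_rates(pred, truth); ro <- oracle_rates(pred, truth)
    expect_equal(r$tpr, ro$tpr, tolerance = 1e-12)
    expect_equal(r$fpr, ro$fpr, tolerance = 1e-12)
    expect_identical(label_clusters_26(pred)$n_clusters,
                     oracle_clusters(pred)$n_clusters)
    cm <- cluster_metrics(pred, truth); co <- oracle_cluster_metrics(pred, truth)
    expect_equal(cm$cluster_tpr, co$cluster_tpr, tolerance = 1e-12)
    expect_equal(cm$cluster_precision, co$cluster_precision, tolerance = 1e-12)
    expect_equal(cm$cluster_f1, co$cluster_f1, tolerance = 1e-12)
  }
})

test_that("paired permutation test is exact under full enumeration", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  expect_equal(paired_permutation_test(a, a)$p, 1)
  # constant positive difference, n = 10: only the identity and the full
  # flip reach |T_obs| -> p = 2 / 1024
  b <- a - 0.3
  pt <- paired_permutation_test(a, b)
  expect_true(pt$exact)
  expect_equal(pt$p, 2 / 1024)
  # max-T corrected p-values never fall below uncorrected
  d1 <- c(0.3, 0.2, 0.4, 0.1, 0.25, 0.3, 0.15, 0.2, 0.35, 0.3)
  fam <- cbind(a - d1, a - 0.5 * d1, a + 0.1 * d1)
  ptf <- paired_permutation_test(a, fam)
  expect_true(all(ptf$p_corrected >= ptf$p - 1e-12))
  expect_error(paired_permutation_test(1:3, 1:4), "equal length")
})

test_that("domain probe is near chance on iid features, high when separable", {
  rng <- rng_make(11)
  n <- 400
  feats <- matrix(rng_norm(rng, n * 5), n, 5)
  doms <- rep(c("a", "b"), each = n / 2)
  acc <- domain_accuracy_probe(feats, doms, seed = 1)
  # binomial null on the held-out half: 0.5 +- 3 * sqrt(0.25 / 200)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / (n / 2)) + 0.02)
  sep <- feats; sep[doms == "b", 1] <- sep[doms == "b", 1] + 8
  expect_gt(domain_accuracy_probe(sep, doms, seed = 1), 0.95)
  expect_equal(domain_accuracy_probe(sep, doms, seed = 3),
               domain_accuracy_probe(sep, doms, seed = 3))
  expect_error(domain_accuracy_probe(feats, rep("a", n)), "2 domains")
})
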