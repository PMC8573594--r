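# Shared fixtures: everything is generated in code at test time.

# tiny domain spec used across modules (fast to generate, still has lesions)
tiny_spec <- function(...) {
  args <- utils::modifyList(list(volume_shape = c(24, 24, 24),
                                 lesion_count_range = c(2, 5),
                                 lesion_radius_range = c(1.5, 2.8)),
                            list(...))
  do.call(domain_spec, args)
}

# tiny network configuration (depth 3, narrow)
tiny_unet_config <- function(base = 4, bott = 16)
  planar_unet_config(depth = 3, base_channels = base, bottleneck_channels = bott)

tiny_ensemble <- function(planes = "axial", seed = 1, base = 4, bott = 16,
                          dims = c(24, 24))
  build_triplanar_ensemble(tiny_unet_config(base, bott),
                           plane_resize_dims(axial = dims, sagittal = dims,
                                             coronal = dims),
                           planes = planes, seed = seed)

# memoised tiny cohort (generation costs ~1 s/subject)
.fixture_cache <- new.env()
tiny_cohort <- function(n = 3, seed = 7) {
  key <- paste0("cohort_", n, "_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- generate_cohort(tiny_spec(), n, seed)
  .fixture_cache[[key]]
}

# random binary 3D mask with tunable density
random_mask <- function(dims, p, seed) {
  rng <- rng_make(seed)
  array(as.numeric(rng_unif(rng, prod(dims)) < p), dims)
}

# ---- independent brute-force metric oracles (double loops, no reuse of ----
# ---- package internals) ---------------------------------------------------

oracle_dice <- function(pred, truth) {
  tp <- 0; np <- 0; nt <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1) np <- np + 1
    if (truth[i] == 1) nt <- nt + 1
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
  }
  if (np + nt == 0) return(1)
  2 * tp / (np + nt)
}

oracle_rates <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  nt <- sum(truth == 1)
  nn <- sum(truth == 0)
  list(tpr = if (nt == 0) NA_real_ else tp / nt,
       fpr = if (nn == 0) NA_real_ else fp / nn)
}

# O(n^2) union-find over foreground voxels, 26-connectivity
oracle_clusters <- function(mask) {
  idx <- which(mask == 1, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) return(list(labels = array(0L, dim(mask)), n_clusters = 0L))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (all(abs(idx[i, ] - idx[j, ]) <= 1)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labs <- match(roots, unique(roots))
  labels <- array(0L, dim(mask))
  labels[mask == 1] <- 0L
  for (i in seq_len(n)) labels[idx[i, 1], idx[i, 2], idx[i, 3]] <- labs[i]
  list(labels = labels, n_clusters = length(unique(roots)))
}

oracle_cluster_metrics <- function(pred, truth) {
  lt <- oracle_clusters(truth); lp <- oracle_clusters(pred)
  tp_t <- 0
  if (lt$n_clusters > 0)
    for (l in seq_len(lt$n_clusters))
      if (any(pred[lt$labels == l] == 1)) tp_t <- tp_t + 1
  tp_p <- 0
  if (lp$n_clusters > 0)
    for (l in seq_len(lp$n_clusters))
      if (any(truth[lp$labels == l] == 1)) tp_p <- tp_p + 1
  tpr <- if (lt$n_clusters == 0) NA_real_ else tp_t / lt$n_clusters
  prec <- if (lp$n_clusters == 0) 0 else tp_p / lp$n_clusters
  t0 <- if (is.na(tpr)) 0 else tpr
  f1 <- if (t0 + prec == 0) 0 else 2 * t0 * prec / (t0 + prec)
  list(cluster_tpr = tpr, cluster_precision = prec, cluster_f1 = f1)
}
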