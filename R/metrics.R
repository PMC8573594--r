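#' Voxel- and cluster-wise WMH evaluation metrics
#'
#' Evaluation suite for binary lesion segmentations: Dice similarity index
#' (SI), voxel-wise true/false positive rates, 26-connected cluster-wise
#' TPR/precision/F1, and the absolute log-transformed volume difference
#' (lAVD). Cluster metrics treat a connected component as detected when it
#' overlaps the other mask by at least one voxel (the usual convention in the
#' WMH challenge literature).
#'
#' @name wmhda-metrics
NULL

check_binary_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) && !is.numeric(x))
    stop(name, " must be a numeric/logical array")
  v <- as.vector(x)
  if (anyNA(v)) stop(name, " contains NA")
  if (!all(v %in% c(0, 1))) stop(name, " must be binary (0/1)")
  invisible(TRUE)
}

check_same_shape <- function(a, b) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db)))
    stop("mask shapes differ: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dice similarity index between two binary masks
#'
#' `SI = 2 TP / (|truth| + |prediction|)`. Defined as 1 when both masks are
#' empty (perfect agreement on "no lesion").
#'
#' @param pred,truth binary arrays of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_si <- function(pred, truth) {
  check_binary_mask(pred); check_binary_mask(truth); check_same_shape(pred, truth)
  p <- sum(pred); t <- sum(truth)
  if (p == 0 && t == 0) return(1)
  tp <- sum(pred * truth)
  2 * tp / (t + p)
}

#' Voxel-wise true and false positive rates
#'
#' TPR = TP / |true WMH voxels|; FPR = FP / |non-WMH voxels|. The FPR
#' denominator is every voxel outside the true mask, restricted to
#' `brain_mask` when one is given. An empty true mask makes the TPR
#' undefined: it is returned as `NA` (flagged, not silently zero).
#'
#' @param pred,truth binary arrays of identical shape.
#' @param brain_mask optional binary array restricting the FPR denominator.
#' @return named list with `tpr` and `fpr`.
#' @export
voxel_rates <- function(pred, truth, brain_mask = NULL) {
  check_binary_mask(pred); check_binary_mask(truth); check_same_shape(pred, truth)
  if (!is.null(brain_mask)) {
    check_binary_mask(brain_mask); check_same_shape(pred, brain_mask)
  }
  tp <- sum(pred * truth)
  nt <- sum(truth)
  tpr <- if (nt == 0) NA_real_ else tp / nt
  if (is.null(brain_mask)) {
    neg <- length(truth) - nt
    fp <- sum(pred * (1 - truth))
  } else {
    neg <- sum(brain_mask * (1 - truth))
    fp <- sum(pred * brain_mask * (1 - truth))
  }
  fpr <- if (neg == 0) NA_real_ else fp / neg
  list(tpr = tpr, fpr = fpr)
}

# 26-neighbourhood offsets as an integer matrix (26 x 3)
neigh26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
})

#' Label 26-connected components of a 3D binary mask
#'
#' Two foreground voxels belong to the same cluster when they share a face,
#' edge, or corner (26-connectivity). Implemented as a vectorised flood fill
#' over linear indices.
#'
#' @param mask binary 3D array.
#' @return list with `labels` (integer array, 0 = background) and `n_clusters`.
#' @export
label_clusters_26 <- function(mask) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array")
  check_binary_mask(mask)
  d <- dim(mask)
  labels <- array(0L, d)
  fg <- which(mask == 1)
  if (length(fg) == 0) return(list(labels = labels, n_clusters = 0L))
  # linear-index offsets of the 26 neighbours; validity checked via coordinates
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  is_fg <- array(FALSE, d); is_fg[fg] <- TRUE
  visited <- array(FALSE, d)
  lab <- 0L
  for (start in fg) {
    if (visited[start]) next
    lab <- lab + 1L
    frontier <- start
    visited[start] <- TRUE
    labels[start] <- lab
    while (length(frontier) > 0) {
      # coordinates of the frontier
      i0 <- frontier - 1L
      x <- i0 %% nx
      y <- (i0 %/% nx) %% ny
      z <- i0 %/% (nx * ny)
      nb <- integer(0)
      for (k in seq_len(nrow(neigh26))) {
        xx <- x + neigh26[k, 1]; yy <- y + neigh26[k, 2]; zz <- z + neigh26[k, 3]
        ok <- xx >= 0 & xx < nx & yy >= 0 & yy < ny & zz >= 0 & zz < nz
        if (!any(ok)) next
        idx <- xx[ok] + nx * (yy[ok] + ny * zz[ok]) + 1L
        nb <- c(nb, idx[is_fg[idx] & !visited[idx]])
      }
      nb <- unique(nb)
      if (length(nb) > 0) {
        visited[nb] <- TRUE
        labels[nb] <- lab
      }
      frontier <- nb
    }
  }
  list(labels = labels, n_clusters = lab)
}

#' Cluster-wise detection metrics
#'
#' A true cluster counts as a true positive when it overlaps at least one
#' predicted voxel; a predicted cluster counts as a true positive when it
#' overlaps at least one true voxel. `cluster_tpr` = TP true clusters /
#' number of true clusters; `cluster_precision` = TP predicted clusters /
#' number of predicted clusters; F1 is their harmonic mean with the
#' degenerate rule F1 = 0 when TPR + precision = 0. With no predicted
#' clusters precision is 0 for F1 purposes; with no true clusters TPR is NA.
#'
#' @param pred,truth binary 3D arrays.
#' @return list with `cluster_tpr`, `cluster_precision`, `cluster_f1`,
#'   `n_true_clusters`, `n_pred_clusters`, `n_tp_clusters`.
#' @export
cluster_metrics <- function(pred, truth) {
  check_binary_mask(pred); check_binary_mask(truth); check_same_shape(pred, truth)
  lt <- label_clusters_26(truth)
  lp <- label_clusters_26(pred)
  tp_true <- if (lt$n_clusters == 0) 0L else
    length(unique(lt$labels[lt$labels > 0 & pred == 1]))
  tp_pred <- if (lp$n_clusters == 0) 0L else
    length(unique(lp$labels[lp$labels > 0 & truth == 1]))
  tpr <- if (lt$n_clusters == 0) NA_real_ else tp_true / lt$n_clusters
  prec <- if (lp$n_clusters == 0) 0 else tp_pred / lp$n_clusters
  tpr_f <- if (is.na(tpr)) 0 else tpr
  f1 <- if ((tpr_f + prec) == 0) 0 else 2 * tpr_f * prec / (tpr_f + prec)
  list(cluster_tpr = tpr, cluster_precision = prec, cluster_f1 = f1,
       n_true_clusters = lt$n_clusters, n_pred_clusters = lp$n_clusters,
       n_tp_clusters = tp_true)
}

#' Absolute log-transformed volume difference
#'
#' `lAVD = |log(V_pred / V_true)|` with the natural logarithm. Volumes must
#' be strictly positive; a zero volume is a degenerate case and raises an
#' error rather than returning an arbitrary value.
#'
#' @param pred_volume,true_volume lesion volumes (e.g. mm^3), both > 0.
#' @return non-negative scalar.
#' @export
lavd <- function(pred_volume, true_volume) {
  if (!is.finite(pred_volume) || !is.finite(true_volume))
    stop("volumes must be finite")
  if (pred_volume <= 0 || true_volume <= 0)
    stop("lAVD undefined for zero/negative volume (degenerate case)")
  abs(log(pred_volume / true_volume))
}

#' Evaluate one subject's predicted mask against the reference
#'
#' Computes all metrics on a pair of co-registered binary masks. Volumes are
#' converted to mm^3 via `voxel_dims`.
#'
#' @param pred,truth binary 3D arrays.
#' @param voxel_dims numeric length-3 voxel dimensions in mm (default 1 mm
#'   isotropic).
#' @param brain_mask optional binary array for the voxel FPR denominator.
#' @return a one-row `data.frame` (class `wmhda_metrics`) with columns `si`,
#'   `voxel_tpr`, `voxel_fpr`, `cluster_tpr`, `cluster_precision`,
#'   `cluster_f1`, `lavd`, `n_true_clusters`, `n_pred_clusters`,
#'   `n_tp_clusters`.
#' @export
evaluate_subject <- function(pred, truth, voxel_dims = c(1, 1, 1),
                             brain_mask = NULL) {
  stopifnot(length(voxel_dims) == 3, all(voxel_dims > 0))
  vr <- voxel_rates(pred, truth, brain_mask)
  cm <- cluster_metrics(pred, truth)
  vox_mm3 <- prod(voxel_dims)
  vp <- sum(pred) * vox_mm3
  vt <- sum(truth) * vox_mm3
  la <- if (vp > 0 && vt > 0) lavd(vp, vt) else NA_real_
  out <- data.frame(
    si = dice_si(pred, truth),
    voxel_tpr = vr$tpr, voxel_fpr = vr$fpr,
    cluster_tpr = cm$cluster_tpr,
    cluster_precision = cm$cluster_precision,
    cluster_f1 = cm$cluster_f1,
    lavd = la,
    n_true_clusters = cm$n_true_clusters,
    n_pred_clusters = cm$n_pred_clusters,
    n_tp_clusters = cm$n_tp_clusters
  )
  class(out) <- c("wmhda_metrics", class(out))
  out
}

#' Paired sign-flip permutation test
#'
#' Two-sided test of zero median/mean paired difference by sign flipping.
#' With `n <= max_exact` paired observations all `2^n` sign assignments are
#' enumerated (exact p-value); otherwise `n_permutations` random flips are
#' drawn (the identity flip is always included). The test statistic is the
#' mean difference.
#'
#' When `b` is a matrix (columns = members of a family of tests, e.g. metric
#' x strategy pairs) the function also returns max-T corrected p-values:
#' `p_corr[j] = P(max_k |T*_k| >= |T_j|)` under the same sign flips.
#'
#' @param a,b paired vectors (or `b` a matrix whose first column pairs with
#'   `a`... see Details) — in the common case both are numeric vectors of
#'   equal length.
#' @param n_permutations random flips when enumeration is infeasible.
#' @param seed integer seed for the random flips.
#' @param max_exact enumerate fully when `n <= max_exact` (default 14).
#' @return list with `p` (uncorrected), `statistic` (observed mean
#'   difference), `exact` (logical), and when a family is supplied,
#'   `p_corrected`.
#' @export
paired_permutation_test <- function(a, b, n_permutations = 10000, seed = 0,
                                    max_exact = 14) {
  if (length(a) != NROW(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs")
  d <- as.matrix(a - b)  # n x m family of differences (m = 1 usually)
  m <- ncol(d)
  tobs <- colMeans(d)
  exact <- (n <= max_exact) && (2^n <= max(n_permutations, 2^n))
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    exact <- TRUE
  } else {
    rng <- rng_make(seed)
    signs <- matrix(sample_signs(rng, n_permutations * n), n_permutations, n)
    signs[1, ] <- 1  # include identity
    exact <- FALSE
  }
  tperm <- abs(signs %*% d) / n  # (n_perm x m) permuted |mean difference|
  eps <- 1e-12
  p <- vapply(seq_len(m), function(j)
    mean(tperm[, j] >= abs(tobs[j]) - eps), numeric(1))
  out <- list(p = if (m == 1) p[[1]] else p, statistic = tobs, exact = exact)
  if (m > 1) {
    tmax <- apply(tperm, 1, max)
    out$p_corrected <- vapply(seq_len(m), function(j)
      mean(tmax >= abs(tobs[j]) - eps), numeric(1))
  }
  out
}

sample_signs <- function(rng, k) {
  ifelse(rng_unif(rng, k) < 0.5, -1, 1)
}

#' Feature-space domain-accuracy probe
#'
#' Trains a small ridge-penalised logistic classifier to predict the domain
#' label from feature vectors, on a stratified random half of the samples,
#' and reports held-out accuracy. Accuracy near 0.5 (chance for two balanced
#' domains) indicates domain-invariant features ("maximal confusion");
#' accuracy near 1 indicates a strong residual domain signal.
#'
#' @param features numeric matrix, one row per sample.
#' @param domains vector of domain labels with exactly 2 levels.
#' @param seed integer seed for the stratified split.
#' @param train_fraction fraction of each domain used for training.
#' @param ridge L2 penalty of the logistic probe.
#' @return held-out accuracy in `[0, 1]`.
#' @export
domain_accuracy_probe <- function(features, domains, seed = 0,
                                  train_fraction = 0.5, ridge = 1e-2) {
  features <- as.matrix(features)
  domains <- as.factor(domains)
  if (nlevels(domains) != 2) stop("need exactly 2 domains")
  if (min(table(domains)) < 2) stop("need >= 2 samples per domain")
  y <- as.integer(domains) - 1L
  rng <- rng_make(seed)
  tr <- logical(nrow(features))
  for (lev in 0:1) {
    idx <- which(y == lev)
    ntr <- max(1L, floor(train_fraction * length(idx)))
    ord <- rng_sample(rng, length(idx))
    tr[idx[ord[seq_len(ntr)]]] <- TRUE
  }
  if (!any(!tr)) stop("empty held-out set")
  fit <- ridge_logistic(features[tr, , drop = FALSE], y[tr], lambda = ridge)
  xte <- cbind(1, scale(features[!tr, , drop = FALSE],
                        center = fit$center, scale = fit$scale))
  pred <- as.integer(drop(xte %*% fit$coef) > 0)
  mean(pred == y[!tr])
}

# Ridge-penalised logistic regression via IRLS on standardised features.
# Deterministic, no dependencies; intercept unpenalised.
ridge_logistic <- function(x, y, lambda = 1e-2, iters = 50, tol = 1e-8) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  xs <- cbind(1, scale(x, center = ctr, scale = scl))
  p <- ncol(xs)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (it in seq_len(iters)) {
    eta <- drop(xs %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    xtw <- t(xs * w)
    beta_new <- solve(xtw %*% xs + pen, xtw %*% z)
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  list(coef = drop(beta), center = ctr, scale = scl)
}
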