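#' Synthetic two-domain FLAIR/T1 lesion cohorts
#'
#' Seeded generator of brain-like volumes with bright white-matter lesions,
#' used to emulate the scanner/population shifts that domain adaptation must
#' overcome: differences in tissue contrast, bias fields, noise level, slice
#' anisotropy and lesion load. The anatomy is deliberately schematic (an
#' ellipsoidal brain with an ellipsoidal ventricle cavity); what matters for
#' the adaptation benchmark is that lesions are bright on FLAIR, that the
#' two "scanners" differ systematically, and that everything is reproducible
#' from a root seed with per-subject stream splitting.
#'
#' @name wmhda-synthgen
NULL

#' Domain specification for the synthetic generator
#'
#' @param name domain label carried by every generated subject.
#' @param volume_shape integer length-3 volume shape in voxels.
#' @param tissue_means named numeric: `background`, `brain`, `ventricle`,
#'   `lesion` mean intensities (arbitrary units).
#' @param bias_amplitude smooth multiplicative bias field amplitude, as a
#'   fraction of the brain mean.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param lesion_count_range integer interval for the number of lesions.
#' @param lesion_radius_range lesion radius interval in voxels.
#' @param periventricular_fraction probability in `[0, 1]` that a lesion
#'   seeds on the dilated ventricle surface rather than uniformly in brain.
#' @param anisotropy per-axis Gaussian smoothing sigmas (voxels) applied to
#'   the intensity images, emulating thick-slice acquisitions; 0 = none.
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(name = "source",
                        volume_shape = c(48, 64, 48),
                        tissue_means = c(background = 0, brain = 100,
                                         ventricle = 40, lesion = 170),
                        bias_amplitude = 0.08,
                        noise_sigma = 5,
                        lesion_count_range = c(3, 8),
                        lesion_radius_range = c(1.6, 3.5),
                        periventricular_fraction = 0.5,
                        anisotropy = c(0, 0, 0)) {
  stopifnot(length(volume_shape) == 3, all(volume_shape >= 8),
            all(is.finite(tissue_means)),
            all(c("background", "brain", "ventricle", "lesion") %in%
                  names(tissue_means)),
            periventricular_fraction >= 0, periventricular_fraction <= 1,
            length(lesion_count_range) == 2,
            lesion_count_range[1] <= lesion_count_range[2],
            lesion_count_range[1] >= 0,
            length(lesion_radius_range) == 2,
            lesion_radius_range[1] <= lesion_radius_range[2],
            lesion_radius_range[1] > 0,
            all(anisotropy >= 0), noise_sigma >= 0, bias_amplitude >= 0)
  if (2 * lesion_radius_range[2] >= min(volume_shape))
    stop("lesion_radius_range does not fit inside volume_shape")
  structure(list(name = name, volume_shape = as.integer(volume_shape),
                 tissue_means = tissue_means, bias_amplitude = bias_amplitude,
                 noise_sigma = noise_sigma,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 periventricular_fraction = periventricular_fraction,
                 anisotropy = anisotropy),
            class = "domain_spec")
}

# Separable Gaussian smoothing of a 3D array (zero-padded edges).
gauss_smooth3d <- function(x, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 1e-8) next
    r <- ceiling(3 * s)
    k <- exp(-((-r:r)^2) / (2 * s^2)); k <- k / sum(k)
    x <- axis_conv(x, k, ax)
  }
  x
}

# Convolve along one axis by shift-and-add (kernels are short).
axis_conv <- function(x, k, ax) {
  d <- dim(x); n <- d[ax]; r <- (length(k) - 1) / 2
  out <- array(0, d)
  idx_full <- lapply(d, seq_len)
  for (j in seq_along(k)) {
    off <- j - 1 - r
    src <- idx_full; dst <- idx_full
    lo <- max(1, 1 - off); hi <- min(n, n - off)
    if (lo > hi) next
    dst[[ax]] <- lo:hi
    src[[ax]] <- (lo:hi) + off
    out_slice <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), dst, list(drop = FALSE)))
    out[dst[[1]], dst[[2]], dst[[3]]] <- cur + k[j] * out_slice
  }
  out
}

# Coordinate grids (1-based voxel centres) for a shape.
coord_grids <- function(d) {
  list(x = array(rep(seq_len(d[1]), times = d[2] * d[3]), d),
       y = array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d),
       z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d))
}

ellipsoid_mask <- function(d, centre, semi) {
  g <- coord_grids(d)
  ((g$x - centre[1]) / semi[1])^2 + ((g$y - centre[2]) / semi[2])^2 +
    ((g$z - centre[3]) / semi[3])^2 <= 1
}

#' Generate one synthetic subject
#'
#' Builds an ellipsoidal brain with a darker ventricle cavity, places fuzzy
#' deformed-sphere lesions (bright on FLAIR), applies a smooth bias field,
#' per-axis anisotropic smoothing and additive noise, and derives a T1 image
#' as an inverted-contrast, independently noised companion.
#'
#' @param spec a [domain_spec()].
#' @param seed non-negative integer; the subject is a pure function of
#'   `(spec, seed)`.
#' @param subject_id identifier (default derived from the seed).
#' @return object of class `wmhda_subject`: list with `flair`, `t1`,
#'   `lesion_mask`, `brain_mask` (3D arrays of one shape), `domain`,
#'   `subject_id`, `voxel_dims`.
#' @export
generate_subject <- function(spec, seed, subject_id = NULL) {
  stopifnot(inherits(spec, "domain_spec"), seed >= 0)
  d <- spec$volume_shape
  rng <- rng_make(seed)
  centre <- d / 2 + 0.5
  brain_semi <- 0.42 * d
  if (min(brain_semi) <= spec$lesion_radius_range[2] + 1)
    stop("volume too small to place any lesion inside the brain")
  brain <- ellipsoid_mask(d, centre, brain_semi)
  vent <- ellipsoid_mask(d, centre, pmax(0.12 * d, 1.5) * c(0.8, 1.3, 0.8))
  vent <- vent & brain

  # candidate lesion seeds: brain interior with a radius-dependent margin
  g <- coord_grids(d)
  norm2 <- ((g$x - centre[1]) / brain_semi[1])^2 +
    ((g$y - centre[2]) / brain_semi[2])^2 + ((g$z - centre[3]) / brain_semi[3])^2
  ring <- which(!vent & brain &
                  ((g$x - centre[1]) / (0.12 * d[1] * 0.8 + 2.5))^2 +
                  ((g$y - centre[2]) / (0.12 * d[2] * 1.3 + 2.5))^2 +
                  ((g$z - centre[3]) / (0.12 * d[3] * 0.8 + 2.5))^2 <= 1)

  n_les <- if (spec$lesion_count_range[1] == spec$lesion_count_range[2])
    spec$lesion_count_range[1] else
    rng_int(rng, 1, spec$lesion_count_range[1], spec$lesion_count_range[2])
  alpha <- array(0, d)   # soft lesion membership
  centres <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  for (i in seq_len(n_les)) {
    r <- rng_unif(rng, 1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
    margin <- (r + 1.5) / min(brain_semi)
    deep <- which(!vent & brain & norm2 <= (1 - margin)^2)
    use_pv <- length(ring) > 0 &&
      rng_unif(rng, 1) < spec$periventricular_fraction
    pool <- if (use_pv) intersect(ring, deep) else deep
    if (length(pool) == 0) pool <- deep
    if (length(pool) == 0) stop("volume too small to place any lesion")
    # rejection sampling for separation from previous lesion seeds
    ctr <- NULL
    for (att in 1:40) {
      cand_idx <- pool[rng_int(rng, 1, 1, length(pool))]
      cand <- c(g$x[cand_idx], g$y[cand_idx], g$z[cand_idx])
      if (nrow(centres) == 0 ||
          min(sqrt(rowSums((centres - matrix(cand, nrow(centres), 3,
                                             byrow = TRUE))^2))) >
          (r + max(radii, 0) + 2)) { ctr <- cand; break }
    }
    if (is.null(ctr)) ctr <- cand
    centres <- rbind(centres, ctr); radii <- c(radii, r)
    # deformed sphere with a soft edge, computed in a bounding box
    pad <- ceiling(r + 3)
    lo <- pmax(round(ctr) - pad, 1); hi <- pmin(round(ctr) + pad, d)
    bb <- lapply(1:3, function(a) lo[a]:hi[a])
    db <- vapply(bb, length, integer(1))
    gb <- coord_grids(db)
    dist <- sqrt((gb$x + lo[1] - 1 - ctr[1])^2 + (gb$y + lo[2] - 1 - ctr[2])^2 +
                   (gb$z + lo[3] - 1 - ctr[3])^2)
    pert <- gauss_smooth3d(array(rng_norm(rng, prod(db)), db), rep(1.2, 3))
    pert <- pert * (0.35 * r / max(stats::sd(pert), 1e-8))
    soft <- 1 / (1 + exp(-(r + pert - dist) / 0.35))
    cur <- alpha[bb[[1]], bb[[2]], bb[[3]]]
    alpha[bb[[1]], bb[[2]], bb[[3]]] <- pmax(cur, soft)
  }
  alpha[!brain | vent] <- 0
  lesion <- (alpha > 0.5) * 1

  tm <- spec$tissue_means
  flair <- array(tm[["background"]], d)
  flair[brain] <- tm[["brain"]]
  flair[vent] <- tm[["ventricle"]]
  flair <- flair + alpha * (tm[["lesion"]] - flair)
  t1 <- array(tm[["background"]], d)
  t1[brain] <- tm[["brain"]] * 1.1
  t1[vent] <- tm[["ventricle"]] * 0.6
  t1 <- t1 - 0.5 * alpha * (tm[["lesion"]] - tm[["brain"]])  # lesions dark-ish on T1

  # smooth multiplicative bias field (heavily smoothed low-frequency noise)
  if (spec$bias_amplitude > 0) {
    bias <- gauss_smooth3d(array(rng_norm(rng, prod(d)), d), 0.25 * d)
    bias <- bias / max(stats::sd(bias), 1e-8) * spec$bias_amplitude
    flair <- flair * (1 + bias)
    t1 <- t1 * (1 + bias)
  }
  if (any(spec$anisotropy > 0)) {
    flair <- gauss_smooth3d(flair, spec$anisotropy)
    t1 <- gauss_smooth3d(t1, spec$anisotropy)
  }
  if (spec$noise_sigma > 0) {
    flair <- flair + rng_norm(rng, prod(d), sd = spec$noise_sigma)
    t1 <- t1 + rng_norm(rng, prod(d), sd = spec$noise_sigma)
  }
  structure(list(flair = flair, t1 = t1, lesion_mask = lesion,
                 brain_mask = brain * 1,
                 domain = spec$name,
                 subject_id = subject_id %||% sprintf("%s_s%d", spec$name, seed),
                 voxel_dims = c(1, 1, 1)),
            class = "wmhda_subject")
}

#' Generate a cohort of subjects from one domain spec
#'
#' Subject seeds are split from the root seed with [derive_seed()], so
#' subject `i` is identical whatever `n` is.
#'
#' @param spec a [domain_spec()].
#' @param n number of subjects (>= 1).
#' @param seed root seed.
#' @return list of `wmhda_subject`, ids `<name>_001`, ...
#' @export
generate_cohort <- function(spec, n, seed = 0) {
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i)
    generate_subject(spec, derive_seed(seed, i),
                     subject_id = sprintf("%s_%03d", spec$name, i)))
}

#' Construct a source/target domain-spec pair from a shift
#'
#' The target spec differs from the base by a multiplicative intensity
#' scale, a lesion-contrast scale (contrast relative to brain tissue),
#' additive bias/noise/anisotropy offsets and a lesion-load offset.
#'
#' @param base a [domain_spec()]; becomes the source (renamed `"source"`).
#' @param shift named list; recognised fields (all optional):
#'   `intensity_scale` (default 1), `contrast_scale` (1), `bias` (0),
#'   `noise` (0), `anisotropy` (c(0,0,0)), `lesion_count` (c(0,0)),
#'   `lesion_radius` (c(0,0)), `periventricular` (0).
#' @return list with elements `source` and `target`.
#' @export
make_domain_pair <- function(base, shift = list()) {
  defaults <- list(intensity_scale = 1, contrast_scale = 1, bias = 0,
                   noise = 0, anisotropy = c(0, 0, 0),
                   lesion_count = c(0, 0), lesion_radius = c(0, 0),
                   periventricular = 0)
  unknown <- setdiff(names(shift), names(defaults))
  if (length(unknown) > 0) stop("unknown shift fields: ", paste(unknown, collapse = ", "))
  s <- utils::modifyList(defaults, shift)
  stopifnot(all(vapply(s, function(v) all(is.finite(v)), logical(1))))
  src <- base; src$name <- "source"
  tm <- base$tissue_means
  # contrast scaling first (relative to brain), then global intensity scale
  tm[["lesion"]] <- tm[["brain"]] + s$contrast_scale * (tm[["lesion"]] - tm[["brain"]])
  tm <- tm * s$intensity_scale
  tgt <- base
  tgt$name <- "target"
  tgt$tissue_means <- tm
  tgt$bias_amplitude <- max(0, base$bias_amplitude + s$bias)
  tgt$noise_sigma <- max(0, base$noise_sigma + s$noise)
  tgt$anisotropy <- pmax(0, base$anisotropy + s$anisotropy)
  tgt$lesion_count_range <- pmax(0L, base$lesion_count_range + as.integer(s$lesion_count))
  tgt$lesion_radius_range <- pmax(0.5, base$lesion_radius_range + s$lesion_radius)
  tgt$periventricular_fraction <-
    min(1, max(0, base$periventricular_fraction + s$periventricular))
  list(source = src, target = tgt)
}

#' Write a cohort to disk as NIfTI files with a CSV manifest
#'
#' Files per subject: `<id>_flair.nii.gz`, `<id>_t1.nii.gz`,
#' `<id>_mask.nii.gz`, `<id>_brain.nii.gz`; manifest columns: subject_id,
#' domain, flair, t1, mask, brain.
#'
#' @param cohort list of `wmhda_subject`.
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    pth <- function(kind) file.path(dir, sprintf("%s_%s.nii.gz", s$subject_id, kind))
    nifti_write(s$flair, pth("flair"), s$voxel_dims)
    nifti_write(s$t1, pth("t1"), s$voxel_dims)
    nifti_write(s$lesion_mask, pth("mask"), s$voxel_dims, datatype = "uint8")
    nifti_write(s$brain_mask, pth("brain"), s$voxel_dims, datatype = "uint8")
    data.frame(subject_id = s$subject_id, domain = s$domain,
               flair = pth("flair"), t1 = pth("t1"), mask = pth("mask"),
               brain = pth("brain"))
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a cohort back from a manifest CSV
#'
#' @param manifest path to a manifest written by [write_cohort()].
#' @return list of `wmhda_subject`.
#' @export
read_cohort <- function(manifest) {
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    fl <- nifti_read(tab$flair[i])
    structure(list(flair = fl$data,
                   t1 = nifti_read(tab$t1[i])$data,
                   lesion_mask = nifti_read(tab$mask[i])$data,
                   brain_mask = nifti_read(tab$brain[i])$data,
                   domain = tab$domain[i], subject_id = tab$subject_id[i],
                   voxel_dims = fl$pixdim),
              class = "wmhda_subject")
  })
}
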