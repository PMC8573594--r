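#' Preprocessing: normalisation, FOV cropping, planar slicing, reassembly
#'
#' Implements the preprocessing contract from brain-extracted, co-registered
#' volumes onward. Upstream steps (brain extraction, bias-field correction,
#' registration, reorientation) are a precondition of the input, not
#' implemented here. Axis convention: volumes are `(x, y, z)`; axial slices
#' are fixed-`z` planes of shape `(x, y)`, sagittal fixed-`x` planes `(y, z)`,
#' coronal fixed-`y` planes `(x, z)`.
#'
#' @name wmhda-preproc
NULL

PLANES <- c("axial", "sagittal", "coronal")

# normal axis and in-plane axes for each plane
plane_axes <- function(plane) {
  switch(plane,
         axial    = list(normal = 3L, inplane = c(1L, 2L)),
         sagittal = list(normal = 1L, inplane = c(2L, 3L)),
         coronal  = list(normal = 2L, inplane = c(1L, 3L)),
         stop("unknown plane: ", plane))
}

#' Gaussian intensity normalisation within the brain mask
#'
#' Shifts and scales the volume so that voxels inside the brain mask have
#' mean 0 and standard deviation 1; voxels outside the mask are set to 0.
#' Statistics are computed inside the mask only.
#'
#' @param volume 3D intensity array (finite values).
#' @param brain_mask binary array of the same shape, nonempty.
#' @return normalised 3D array.
#' @export
gaussian_normalise <- function(volume, brain_mask) {
  check_same_shape(volume, brain_mask)
  if (!all(is.finite(volume))) stop("volume contains non-finite values")
  inside <- brain_mask > 0
  if (!any(inside)) stop("empty brain mask")
  v <- volume[inside]
  s <- stats::sd(v)
  if (!is.finite(s) || s < 1e-12)
    stop("constant-intensity volume inside mask: normalisation undefined")
  # population sd (divide by n) so the post-condition holds exactly
  s <- sqrt(mean((v - mean(v))^2))
  out <- array(0, dim(volume))
  out[inside] <- (v - mean(v)) / s
  out
}

#' Crop the field of view to the brain bounding box
#'
#' @param volume 3D array.
#' @param brain_mask nonempty binary array of the same shape.
#' @param margin voxels of padding around the mask bounding box; the padded
#'   box is clipped to the volume.
#' @return list with `volume` (cropped array) and `crop_box` (2x3 matrix of
#'   inclusive lo/hi indices per axis).
#' @export
crop_fov <- function(volume, brain_mask, margin = 2) {
  check_same_shape(volume, brain_mask)
  idx <- which(brain_mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty brain mask")
  lo <- pmax(apply(idx, 2, min) - margin, 1)
  hi <- pmin(apply(idx, 2, max) + margin, dim(volume))
  box <- rbind(lo = lo, hi = hi)
  list(volume = volume[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       crop_box = box)
}

#' Extract (and resize) the 2D slices of a volume along one plane
#'
#' Slices are ordered by ascending index along the plane's normal axis.
#' Intensity images are resized bilinearly; masks/labels should use
#' `interpolation = "nearest"` and are re-binarised when binary input is
#' detected.
#'
#' @param volume cropped (and, for images, normalised) 3D array.
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param resize_dims target `(rows, cols)` per slice, or `NULL` for no
#'   resizing.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param original_shape shape of the uncropped volume (for reassembly).
#' @param crop_box 2x3 crop box from [crop_fov()] (for reassembly).
#' @return object of class `plane_slice_stack`: list with `plane`, `slices`
#'   (list of 2D matrices), `native_dims`, `resize_dims`, `original_shape`,
#'   `crop_box`.
#' @export
extract_plane_slices <- function(volume, plane, resize_dims = NULL,
                                 interpolation = c("bilinear", "nearest"),
                                 original_shape = dim(volume),
                                 crop_box = rbind(lo = c(1, 1, 1), hi = dim(volume))) {
  if (!plane %in% PLANES) stop("unknown plane: ", plane)
  interpolation <- match.arg(interpolation)
  ax <- plane_axes(plane)
  d <- dim(volume)
  n <- d[ax$normal]
  native <- d[ax$inplane]
  binary_in <- all(volume %in% c(0, 1))
  slices <- lapply(seq_len(n), function(k) {
    sl <- switch(plane,
                 axial = volume[, , k],
                 sagittal = volume[k, , ],
                 coronal = volume[, k, ])
    if (!is.null(resize_dims)) {
      sl <- resize2d(sl, resize_dims, method = interpolation)
      if (interpolation == "nearest" && binary_in) sl <- (sl > 0.5) * 1
    }
    sl
  })
  structure(list(plane = plane, slices = slices, native_dims = native,
                 resize_dims = resize_dims %||% native,
                 original_shape = as.integer(original_shape),
                 crop_box = crop_box),
            class = "plane_slice_stack")
}

#' Reassemble planar probability slices into a 3D volume
#'
#' The inverse of [extract_plane_slices()] for probability maps: each slice
#' is bilinearly resized back to its native in-plane dimensions, slices are
#' stacked along the plane's normal axis, the stack is embedded at the crop
#' box within a zero background of the original shape, and values are
#' clipped to `[0, 1]`.
#'
#' @param stack a `plane_slice_stack` whose slices hold per-pixel
#'   probabilities.
#' @return 3D probability array of shape `stack$original_shape`.
#' @export
assemble_probability_volume <- function(stack) {
  stopifnot(inherits(stack, "plane_slice_stack"))
  ax <- plane_axes(stack$plane)
  box <- stack$crop_box
  crop_dims <- box["hi", ] - box["lo", ] + 1
  n_expected <- crop_dims[ax$normal]
  if (length(stack$slices) != n_expected)
    stop("slice count (", length(stack$slices), ") does not match crop box (",
         n_expected, ")")
  native <- crop_dims[ax$inplane]
  cropped <- array(0, crop_dims)
  for (k in seq_along(stack$slices)) {
    sl <- resize2d(stack$slices[[k]], native, method = "bilinear")
    switch(stack$plane,
           axial = cropped[, , k] <- sl,
           sagittal = cropped[k, , ] <- sl,
           coronal = cropped[, k, ] <- sl)
  }
  cropped <- pmin(pmax(cropped, 0), 1)
  out <- array(0, stack$original_shape)
  out[box["lo", 1]:box["hi", 1], box["lo", 2]:box["hi", 2],
      box["lo", 3]:box["hi", 3]] <- cropped
  out
}

#' Default per-plane slice dimensions
#'
#' Standard-resolution MNI-space defaults: axial 128x192, sagittal 192x120,
#' coronal 128x80. Synthetic cohorts use smaller volumes, so the dims are
#' configurable everywhere; all dims must be divisible by
#' `2^(depth - 1)` of the network.
#'
#' @param axial,sagittal,coronal `(rows, cols)` integer pairs.
#' @return named list of resize dims per plane.
#' @export
plane_resize_dims <- function(axial = c(128, 192), sagittal = c(192, 120),
                              coronal = c(128, 80)) {
  list(axial = axial, sagittal = sagittal, coronal = coronal)
}

#' Full image-side preprocessing of one subject for one plane
#'
#' Normalises both modalities inside the brain mask, crops the FOV, extracts
#' and resizes the plane's slices (bilinear for images, nearest for masks).
#' A subject without a `lesion_mask` (unlabelled target data) yields an
#' all-zero label stack and is flagged `has_label = FALSE`.
#'
#' @param subject a `wmhda_subject`.
#' @param plane plane name.
#' @param resize_dims per-slice `(rows, cols)`.
#' @param crop_margin FOV margin in voxels.
#' @param keep `"all"` slices or only those containing `"brain"`.
#' @return list with `x` (array `(H, W, 2, n)`), `y` (`(H, W, n)`),
#'   `slice_index`, `n_slices`, `crop_box`, `original_shape`, `plane`,
#'   `template_stack`, `has_label`.
#' @export
preprocess_subject_plane <- function(subject, plane, resize_dims,
                                     crop_margin = 2, keep = c("all", "brain")) {
  keep <- match.arg(keep)
  fl <- gaussian_normalise(subject$flair, subject$brain_mask)
  t1 <- gaussian_normalise(subject$t1, subject$brain_mask)
  cr <- crop_fov(fl, subject$brain_mask, margin = crop_margin)
  box <- cr$crop_box
  sub3 <- function(v) v[box["lo", 1]:box["hi", 1], box["lo", 2]:box["hi", 2],
                        box["lo", 3]:box["hi", 3], drop = FALSE]
  orig <- dim(subject$flair)
  st_fl <- extract_plane_slices(cr$volume, plane, resize_dims, "bilinear",
                                original_shape = orig, crop_box = box)
  st_t1 <- extract_plane_slices(sub3(t1), plane, resize_dims, "bilinear",
                                original_shape = orig, crop_box = box)
  has_label <- !is.null(subject$lesion_mask)
  lab_vol <- if (has_label) sub3(subject$lesion_mask) else
    array(0, dim(cr$volume))
  st_lab <- extract_plane_slices(lab_vol, plane, resize_dims,
                                 "nearest", original_shape = orig, crop_box = box)
  st_brain <- extract_plane_slices(sub3(subject$brain_mask), plane, resize_dims,
                                   "nearest", original_shape = orig, crop_box = box)
  n <- length(st_fl$slices)
  keep_idx <- seq_len(n)
  if (keep == "brain")
    keep_idx <- which(vapply(st_brain$slices, function(s) any(s > 0), logical(1)))
  h <- resize_dims[1]; w <- resize_dims[2]
  x <- array(0, c(h, w, 2, length(keep_idx)))
  y <- array(0, c(h, w, length(keep_idx)))
  for (j in seq_along(keep_idx)) {
    k <- keep_idx[j]
    x[, , 1, j] <- st_fl$slices[[k]]
    x[, , 2, j] <- st_t1$slices[[k]]
    y[, , j] <- st_lab$slices[[k]]
  }
  list(x = x, y = y, slice_index = keep_idx, n_slices = n,
       crop_box = box, original_shape = orig, plane = plane,
       template_stack = st_fl, has_label = has_label)
}
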