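test_that("gaussian_normalise zeroes moments inside the mask", {
  s <- tiny_cohort(1)[[1]]
  out <- gaussian_normalise(s$flair, s$brain_mask)
  inside <- s$brain_mask == 1
  expect_lt(abs(mean(out[inside])), 1e-6)
  expect_lt(abs(sqrt(mean(out[inside]^2)) - 1), 1e-6)
  expect_true(all(out[!inside] == 0))
  # idempotence
  out2 <- gaussian_normalise(out, s$brain_mask)
  expect_equal(out2, out, tolerance = 1e-10)
  # affine invariance: c + 2 * z recovers z inside the mask
  shifted <- 5 + 2 * out
  expect_equal(gaussian_normalise(shifted, s$brain_mask)[inside], out[inside],
               tolerance = 1e-10)
  expect_error(gaussian_normalise(array(3, dim(s$flair)), s$brain_mask),
               "constant")
  expect_error(gaussian_normalise(s$flair, array(0, dim(s$flair))), "empty")
})

test_that("crop_fov returns the padded clipped bounding box", {
  v <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  full <- array(1, c(8, 8, 8))
  cf <- crop_fov(v, full, margin = 2)
  expect_equal(dim(cf$volume), c(8, 8, 8))
  expect_equal(unname(cf$crop_box["lo", ]), c(1, 1, 1))
  single <- array(0, c(8, 8, 8)); single[3, 5, 2] <- 1
  cs <- crop_fov(v, single, margin = 0)
  expect_equal(dim(cs$volume), c(1, 1, 1))
  expect_equal(cs$volume[1, 1, 1], v[3, 5, 2])
  # property: padded box never exceeds the original shape
  for (seed in 1:10) {
    m <- random_mask(c(8, 8, 8), 0.05, seed)
    if (sum(m) == 0) next
    cb <- crop_fov(v, m, margin = 3)$crop_box
    expect_true(all(cb["lo", ] >= 1) && all(cb["hi", ] <= 8))
    expect_true(all(cb["lo", ] <= cb["hi", ]))
  }
  expect_error(crop_fov(v, array(0, c(8, 8, 8))), "empty")
})

test_that("extract and assemble are mutually inverse without resizing", {
  s <- tiny_cohort(1)[[1]]
  cf <- crop_fov(s$flair, s$brain_mask, margin = 2)
  for (plane in c("axial", "sagittal", "coronal")) {
    st <- extract_plane_slices(cf$volume, plane, resize_dims = NULL,
                               original_shape = dim(s$flair),
                               crop_box = cf$crop_box)
    # probabilities must be in [0, 1] for assembly: use a clipped copy
    stp <- st
    stp$slices <- lapply(st$slices, function(x) pmin(pmax(x / 200, 0), 1))
    vol <- assemble_probability_volume(stp)
    expect_equal(dim(vol), dim(s$flair))
    box <- cf$crop_box
    inner <- vol[box["lo", 1]:box["hi", 1], box["lo", 2]:box["hi", 2],
                 box["lo", 3]:box["hi", 3]]
    expect_equal(inner, pmin(pmax(cf$volume / 200, 0), 1), tolerance = 1e-12)
    # outside the crop box everything is zero
    vol[box["lo", 1]:box["hi", 1], box["lo", 2]:box["hi", 2],
        box["lo", 3]:box["hi", 3]] <- 0
    expect_true(all(vol == 0))
  }
  expect_error(extract_plane_slices(cf$volume, "oblique"), "unknown plane")
})

test_that("resizing contracts: no-op, constants, nearest labels stay binary", {
  v <- array(rnorm(12 * 10 * 8), c(12, 10, 8))
  st <- extract_plane_slices(v, "axial", resize_dims = c(12, 10))
  expect_equal(st$slices[[3]], v[, , 3])      # native dims -> untouched
  cv <- array(4.2, c(12, 10, 8))
  stc <- extract_plane_slices(cv, "axial", resize_dims = c(24, 20))
  expect_true(all(abs(stc$slices[[1]] - 4.2) < 1e-12))
  m <- random_mask(c(12, 10, 8), 0.2, seed = 5)
  stm <- extract_plane_slices(m, "sagittal", resize_dims = c(16, 12),
                              interpolation = "nearest")
  expect_true(all(unlist(stm$slices) %in% c(0, 1)))
})

test_that("assembled probabilities are clipped to [0,1] and shapes checked", {
  v <- array(rnorm(8 * 8 * 8, sd = 3), c(8, 8, 8))
  st <- extract_plane_slices(v, "axial")
  out <- assemble_probability_volume(st)
  expect_true(all(out >= 0 & out <= 1))
  st$slices <- st$slices[-1]
  expect_error(assemble_probability_volume(st), "slice count")
})

test_that("plane geometry: slice order and orientation per plane", {
  v <- array(seq_len(4 * 6 * 8), c(4, 6, 8))
  ax <- extract_plane_slices(v, "axial")
  expect_length(ax$slices, 8)
  expect_equal(ax$slices[[2]], v[, , 2])
  sg <- extract_plane_slices(v, "sagittal")
  expect_length(sg$slices, 4)
  expect_equal(sg$slices[[3]], v[3, , ])
  co <- extract_plane_slices(v, "coronal")
  expect_length(co$slices, 6)
  expect_equal(co$slices[[6]], v[, 6, ])
})
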