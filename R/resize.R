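# Bilinear / nearest-neighbour resampling primitives.
#
# Resizing is expressed as two 1D linear interpolation matrices (rows, cols)
# so that a 2D resize is Y = A X B'. This makes the operation exactly
# invertible book-keeping-wise (identity when dims match), cheap via BLAS,
# and trivially differentiable (the backward pass uses the transposes),
# which the network decoder relies on.

# 1D bilinear interpolation matrix mapping n_in samples to n_out.
# Coordinates are voxel centres; edge values are clamped.
interp_matrix <- function(n_in, n_out) {
  if (n_in == n_out) return(diag(n_out))
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  i0 <- pmin(pmax(floor(pos), 1), n_in)
  frac <- pos - i0
  i1 <- pmin(i0 + 1, n_in)
  frac[i1 == i0] <- 0
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), i0)] <- A[cbind(seq_len(n_out), i0)] + (1 - frac)
  A[cbind(seq_len(n_out), i1)] <- A[cbind(seq_len(n_out), i1)] + frac
  A
}

# memoised interpolation matrices (shapes repeat constantly during training)
.interp_cache <- new.env(parent = emptyenv())
interp_matrix_cached <- function(n_in, n_out) {
  key <- paste0(n_in, "_", n_out)
  m <- .interp_cache[[key]]
  if (is.null(m)) {
    m <- interp_matrix(n_in, n_out)
    .interp_cache[[key]] <- m
  }
  m
}

# nearest-neighbour index map
nearest_index <- function(n_in, n_out) {
  if (n_in == n_out) return(seq_len(n_out))
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  pmin(pmax(round(pos), 1), n_in)
}

#' Resize a 2D matrix
#'
#' @param mat numeric matrix.
#' @param dims target `(rows, cols)`.
#' @param method `"bilinear"` (images) or `"nearest"` (labels/masks).
#' @return resized matrix.
#' @export
resize2d <- function(mat, dims, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (all(dim(mat) == dims)) return(mat)
  if (method == "bilinear") {
    A <- interp_matrix_cached(nrow(mat), dims[1])
    B <- interp_matrix_cached(ncol(mat), dims[2])
    A %*% mat %*% t(B)
  } else {
    mat[nearest_index(nrow(mat), dims[1]), nearest_index(ncol(mat), dims[2]),
        drop = FALSE]
  }
}

# Batched bilinear resize of (H, W, C, N) arrays; backward = same routine
# with transposed interpolation matrices, handled by the caller.
resize_bilinear4d <- function(x, h2, w2, transpose = FALSE) {
  d <- dim(x)
  A <- interp_matrix_cached(if (transpose) h2 else d[1], if (transpose) d[1] else h2)
  B <- interp_matrix_cached(if (transpose) w2 else d[2], if (transpose) d[2] else w2)
  if (transpose) { A <- t(A); B <- t(B) }
  hh <- nrow(A); ww <- nrow(B)
  y <- A %*% matrix(x, d[1], d[2] * d[3] * d[4])          # rows
  dim(y) <- c(hh, d[2], d[3], d[4])
  y <- aperm(y, c(2, 1, 3, 4))
  y <- B %*% matrix(y, d[2], hh * d[3] * d[4])            # cols
  dim(y) <- c(ww, hh, d[3], d[4])
  aperm(y, c(2, 1, 3, 4))
}
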