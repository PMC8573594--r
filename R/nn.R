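# Neural-network primitives with manual backpropagation.
#
# No deep-learning runtime is assumed: layers are small R environments
# holding parameters, gradients and forward caches, and every operation has
# an explicit backward pass. Convolutions are computed as im2col + BLAS
# matrix products; batches are (H, W, C, N) arrays. This is sized for the
# small planar U-Nets this package trains on CPU, not for general use.

new_layer <- function(class, param_names = character(0)) {
  L <- new.env(parent = emptyenv())
  L$class <- class
  L$param_names <- param_names
  L$frozen <- FALSE
  L
}

nn_conv2d <- function(cin, cout, k, pad, rng) {
  L <- new_layer("conv2d", c("W", "b"))
  fan_in <- k * k * cin
  L$W <- array(rng_norm(rng, k * k * cin * cout, sd = sqrt(2 / fan_in)),
               c(k, k, cin, cout))
  L$b <- numeric(cout)
  L$k <- k; L$pad <- pad; L$cin <- cin; L$cout <- cout
  L$gW <- array(0, dim(L$W)); L$gb <- numeric(cout)
  L
}

conv_fw <- function(L, x, keep_cache = TRUE) {
  r <- conv2d_fw_cpp(x, L$W, L$b, L$pad, keep_cache)
  if (keep_cache) { L$M <- r$M; L$xdim <- dim(x) }
  r$y
}

conv_bw <- function(L, dy) {
  r <- conv2d_bw_cpp(L$M, dy, L$W, as.integer(L$xdim), L$pad)
  L$gW <- L$gW + r$gW
  L$gb <- L$gb + as.numeric(r$gb)
  L$M <- NULL
  r$dx
}

nn_bn2d <- function(ch) {
  L <- new_layer("bn2d", c("gamma", "beta"))
  L$gamma <- rep(1, ch); L$beta <- numeric(ch)
  L$rmean <- numeric(ch); L$rvar <- rep(1, ch)
  L$momentum <- 0.1; L$eps <- 1e-5; L$ch <- ch
  L$ggamma <- numeric(ch); L$gbeta <- numeric(ch)
  L
}

bn_fw <- function(L, x, train) {
  d <- dim(x); ch <- d[3]
  m <- d[1] * d[2] * d[4]
  use_batch <- train && !L$frozen
  if (use_batch) {
    mo <- bn_moments_cpp(x)
    mu <- mo$sum / m
    va <- mo$sumsq / m - mu^2
    L$rmean <- (1 - L$momentum) * L$rmean + L$momentum * mu
    L$rvar <- (1 - L$momentum) * L$rvar + L$momentum * va
  } else { mu <- L$rmean; va <- L$rvar }
  ivar <- 1 / sqrt(va + L$eps)
  L$x <- x; L$mu <- mu; L$ivar <- ivar; L$use_batch <- use_batch; L$xdim <- d
  bn_affine_cpp(x, mu, L$gamma * ivar, L$beta)
}

bn_bw <- function(L, dy) {
  d <- L$xdim
  m <- d[1] * d[2] * d[4]
  xhat <- bn_affine_cpp(L$x, L$mu, L$ivar, numeric(length(L$ivar)))
  red <- bn_reduce_cpp(dy, xhat)
  L$ggamma <- L$ggamma + red$sumprod
  L$gbeta <- L$gbeta + red$sum
  if (L$use_batch) {
    # dx = ivar * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat)) per channel
    z <- numeric(length(L$ivar))
    s1 <- red$sum * L$gamma; s2 <- red$sumprod * L$gamma
    dx <- bn_affine_cpp(dy, z, L$gamma * L$ivar, -L$ivar * s1 / m) -
      bn_affine_cpp(xhat, z, L$ivar * s2 / m, z)
  } else {
    dx <- bn_affine_cpp(dy, numeric(length(L$ivar)), L$gamma * L$ivar,
                        numeric(length(L$ivar)))
  }
  L$x <- NULL
  dx
}

nn_maxpool2 <- function() new_layer("maxpool2")

pool_fw <- function(L, x) {
  d <- dim(x)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) stop("maxpool needs even spatial dims")
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  x11 <- x[ro, co, , , drop = FALSE];     x21 <- x[ro + 1, co, , , drop = FALSE]
  x12 <- x[ro, co + 1, , , drop = FALSE]; x22 <- x[ro + 1, co + 1, , , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  L$views <- list(x11, x21, x12, x22); L$y <- y; L$xdim <- d
  y
}

pool_bw <- function(L, dy) {
  d <- L$xdim
  ro <- seq(1, d[1], 2); co <- seq(1, d[2], 2)
  v <- L$views; y <- L$y
  m1 <- v[[1]] == y
  m2 <- (v[[2]] == y) & !m1
  m3 <- (v[[3]] == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  dx <- array(0, d)
  dx[ro, co, , ] <- dy * m1
  dx[ro + 1, co, , ] <- dy * m2
  dx[ro, co + 1, , ] <- dy * m3
  dx[ro + 1, co + 1, , ] <- dy * m4
  L$views <- NULL; L$y <- NULL
  dx
}

nn_linear <- function(din, dout, rng) {
  L <- new_layer("linear", c("W", "b"))
  L$W <- matrix(rng_norm(rng, din * dout, sd = sqrt(2 / din)), din, dout)
  L$b <- numeric(dout)
  L$gW <- matrix(0, din, dout); L$gb <- numeric(dout)
  L
}

linear_fw <- function(L, x) { L$x <- x; x %*% L$W + rep(L$b, each = nrow(x)) }

linear_bw <- function(L, dy) {
  L$gW <- L$gW + crossprod(L$x, dy)
  L$gb <- L$gb + colSums(dy)
  L$x <- NULL
  dy %*% t(L$W)
}

nn_dropout <- function(p, rng) {
  L <- new_layer("dropout")
  L$p <- p; L$rng <- rng
  L
}

dropout_fw <- function(L, x, train) {
  if (!train || L$p <= 0) { L$mask <- NULL; return(x) }
  mask <- (rng_unif(L$rng, length(x)) >= L$p) / (1 - L$p)
  dim(mask) <- dim(x) %||% NULL
  L$mask <- mask
  x * mask
}

dropout_bw <- function(L, dy) if (is.null(L$mask)) dy else dy * L$mask

row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# channel softmax for (H, W, C, N)
softmax_channels <- function(z) {
  d <- dim(z)
  zm <- matrix(aperm(z, c(1, 2, 4, 3)), ncol = d[3])
  zm <- zm - row_max(zm)
  e <- exp(zm)
  pm <- e / rowSums(e)
  aperm(array(pm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# backward through channel softmax given dL/dp and cached p
softmax_channels_bw <- function(p, dp) {
  d <- dim(p)
  pm <- matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3])
  dpm <- matrix(aperm(dp, c(1, 2, 4, 3)), ncol = d[3])
  s <- rowSums(dpm * pm)
  dzm <- pm * (dpm - s)
  aperm(array(dzm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

softmax_rows <- function(z) {
  z <- z - row_max(z)
  e <- exp(z)
  e / rowSums(e)
}

softmax_rows_bw <- function(p, dp) p * (dp - rowSums(dp * p))

# ---- optimisers -----------------------------------------------------------

#' Adam optimiser state
#' @param lr learning rate; @param eps Adam epsilon (default 1e-4).
#' @param beta1,beta2 moment decay rates.
#' @return optimiser object for [opt_step()].
#' @keywords internal
opt_adam <- function(lr = 1e-3, eps = 1e-4, beta1 = 0.9, beta2 = 0.999) {
  o <- new.env(parent = emptyenv())
  o$kind <- "adam"; o$lr <- lr; o$eps <- eps
  o$beta1 <- beta1; o$beta2 <- beta2; o$t <- 0
  o$state <- new.env(parent = emptyenv())
  o
}

# SGD with momentum (domain predictor of the adversarial strategies)
opt_sgdm <- function(lr = 1e-3, momentum = 0.9) {
  o <- new.env(parent = emptyenv())
  o$kind <- "sgdm"; o$lr <- lr; o$momentum <- momentum
  o$state <- new.env(parent = emptyenv())
  o
}

# one update over a named list of layers; frozen layers are skipped entirely
opt_step <- function(opt, layers, lr = opt$lr) {
  if (opt$kind == "adam") opt$t <- opt$t + 1
  for (nm in names(layers)) {
    L <- layers[[nm]]
    if (L$frozen || length(L$param_names) == 0) next
    for (p in L$param_names) {
      g <- L[[paste0("g", p)]]
      key <- paste0(nm, ".", p)
      if (opt$kind == "adam") {
        st <- opt$state[[key]]
        if (is.null(st)) st <- list(m = g * 0, v = g * 0)
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g^2
        opt$state[[key]] <- st
        mhat <- st$m / (1 - opt$beta1^opt$t)
        vhat <- st$v / (1 - opt$beta2^opt$t)
        L[[p]] <- L[[p]] - lr * mhat / (sqrt(vhat) + opt$eps)
      } else {
        vel <- opt$state[[key]]
        if (is.null(vel)) vel <- g * 0
        vel <- opt$momentum * vel - lr * g
        opt$state[[key]] <- vel
        L[[p]] <- L[[p]] + vel
      }
    }
  }
  invisible(NULL)
}

zero_grads <- function(layers) {
  for (L in layers) {
    if (length(L$param_names) == 0) next
    for (p in L$param_names) L[[paste0("g", p)]] <- L[[paste0("g", p)]] * 0
  }
  invisible(NULL)
}

# flat copies of parameters (exact doubles), for freezing contracts and
# checkpointing
layers_param_copy <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    L <- layers[[nm]]
    for (p in L$param_names) out[[paste0(nm, ".", p)]] <- L[[p]]
    if (L$class == "bn2d") {
      out[[paste0(nm, ".rmean")]] <- L$rmean
      out[[paste0(nm, ".rvar")]] <- L$rvar
    }
  }
  out
}

layers_param_restore <- function(layers, saved) {
  for (nm in names(layers)) {
    L <- layers[[nm]]
    for (p in L$param_names) {
      key <- paste0(nm, ".", p)
      if (!is.null(saved[[key]])) L[[p]] <- saved[[key]]
    }
    if (L$class == "bn2d") {
      if (!is.null(saved[[paste0(nm, ".rmean")]])) L$rmean <- saved[[paste0(nm, ".rmean")]]
      if (!is.null(saved[[paste0(nm, ".rvar")]])) L$rvar <- saved[[paste0(nm, ".rvar")]]
    }
  }
  invisible(NULL)
}
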