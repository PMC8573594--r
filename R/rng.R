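# Seeded RNG streams.
#
# All stochastic code in the package draws from explicit stream objects
# rather than the global RNG, so that cohorts, augmentation and training are
# reproducible and cohort membership is stable when n changes (streams are
# split per subject from a root seed). A stream is a captured Mersenne
# Twister state; drawing from it never disturbs the caller's .Random.seed.

#' Create a seeded RNG stream
#'
#' @param seed non-negative integer seed.
#' @return an opaque stream object for the `rng_*` draw functions.
#' @export
rng_make <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% 2147483647), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  expr
}

rng_unif <- function(rng, n, min = 0, max = 1) with_rng(rng, stats::runif(n, min, max))
rng_norm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, stats::rnorm(n, mean, sd))
rng_int  <- function(rng, n, lo, hi) with_rng(rng, lo + floor(stats::runif(n) * (hi - lo + 1)))
rng_sample <- function(rng, n, size = n, replace = FALSE)
  with_rng(rng, sample.int(n, size, replace = replace))

#' Derive a child seed from a root seed
#'
#' Deterministic integer hash used to split independent streams (e.g. one
#' per subject) from a root seed. Result is always in `[0, 2^31 - 2]`.
#'
#' @param seed root seed.
#' @param index stream index (e.g. subject number).
#' @param tag optional extra integer namespace (default 0).
#' @export
derive_seed <- function(seed, index, tag = 0) {
  m <- 2147483647
  h <- (as.numeric(seed) %% m)
  h <- (h * 69069 + as.numeric(index) * 1234567 + as.numeric(tag) * 97 + 12345) %% m
  h <- (h * 69069 + 1) %% m
  h
}
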