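# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

# Derive a stream-specific 31-bit sub-seed so independent stages fed from one
# user seed do not share RNG streams.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(offset) * 97) %%
               2147483562)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

# Exact GeLU: x * Phi(x), Phi the standard normal CDF (equivalently the
# erf form x/2 * (1 + erf(x / sqrt(2)))).
gelu <- function(x) x * pnorm(x)

assert_that_ <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Column-wise z-score; zero-variance columns map to 0 rather than NaN.
zscore_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

minmax_norm <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) < 1e-12) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}
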