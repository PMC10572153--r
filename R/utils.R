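# Internal numeric helpers shared across modules.

# DFT sample frequencies for n samples at spacing d (cycles per mm),
# in FFT (wrap-around) order.
fftFreq <- function(n, d) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Evaluate thunk with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

# Linear interpolation clamped to the end values outside the support.
interpClamp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Derive a bounded child seed from a base seed and a stream index
# (kept below 2^31 - 1 so it is always a valid integer seed).
childSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(stream) + 11) %% 2147483629)
}
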