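# Independent oracles used across the suite. These deliberately avoid the
# package's own radial-quadrature / profile code paths.

# Analytic f50 of a Gaussian blur: solve exp(-2 pi^2 sigma^2 f^2) = 1/2.
gaussF50 <- function(sigma) sqrt(log(2) / 2) / (pi * sigma)

# Brute-force NPWE d-prime on a full 2-D Cartesian frequency grid.
cartesianDprime <- function(task, npsFun, ttfFun = NULL, display = NULL,
                            fmax, n = 801L) {
  u <- seq(-fmax, fmax, length.out = n)
  du <- u[2L] - u[1L]
  fr <- sqrt(outer(u^2, u^2, `+`))
  W <- taskFunction(task, fr)
  Tt <- if (is.null(ttfFun)) 1 else ttfFun(fr)
  E <- if (is.null(display)) 1 else eyeFilter(fr, display)
  N <- npsFun(fr)
  num <- sum(W^2 * Tt^2 * E^2) * du^2
  den <- sum(W^2 * Tt^2 * E^4 * N) * du^2
  num / sqrt(den)
}

# Brute-force local maxima of a sampled curve (strict on the left,
# non-strict on the right, matching a plain grid scan).
bruteLocalMaxima <- function(x, y) {
  n <- length(y)
  i <- 2:(n - 1L)
  idx <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  x[idx]
}

# Hand-rolled percent-difference summary for arbitrary paired tables.
brutePctSummary <- function(a, b) {
  d <- 100 * (a - b) / b
  list(mean = mean(d), sd = stats::sd(d), n = length(d))
}

# A small noise-only stack (no phantom scene) of i.i.d. or shaped noise.
noiseOnlyStack <- function(nSlices, size, spacing, model, seed = 1L) {
  vox <- array(0, c(size, size, nSlices))
  for (k in seq_len(nSlices))
    vox[, , k] <- generateNoiseField(c(size, size), spacing, model,
                                     seed = seed + k)
  ctStack(vox, spacing)
}

# Standard small insert phantom used by the TTF tests: 170 mm section on a
# 256^2 grid at the package's reference pixel pitch.
insertPhantomSpec <- function(sigma, contrast, nSlices = 1L, seed = 1L,
                              size = 256L, spacing = 0.742,
                              insertDiameter = 25) {
  phantomSpec(170, backgroundHU = 35, edgeBlurSigma = sigma,
              nSlices = nSlices, matrixSize = size, pixelSpacing = spacing,
              insert = centeredInsert(contrast, insertDiameter, size, spacing),
              seed = seed)
}
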