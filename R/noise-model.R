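#' Construct a parametric radial noise power spectrum model
#'
#' Builds a [NoiseModel-class] from one or more band-pass components. Each
#' component has radial profile
#' \deqn{S(f) = A \, (f/f_c)^p \exp\{-(p/q)\,[(f/f_c)^q - 1]\}}
#' (amplitude `A` in HU^2 mm^2, peak frequency `fc` in mm^-1, rise exponent
#' `p >= 0`, decay exponent `q > 0`). For `p > 0` the profile is zero at
#' `f = 0`, peaks with value `A` exactly at `fc`, and decays beyond; `p = 0`
#' gives a flat (white) component. Two components with separated `fc`
#' produce a two-peak radial spectrum.
#'
#' @param amplitude numeric vector of component amplitudes, HU^2 mm^2.
#' @param peakFreq numeric vector of component peak frequencies, mm^-1.
#' @param rise,p rise exponents (>= 0); `rise` is recycled to the number of
#'   components.
#' @param decay,q decay exponents (> 0), recycled likewise.
#' @param targetSd optional noise standard deviation in HU; when given, the
#'   synthesized field (and the spectrum used to shape it) is rescaled so
#'   the 2-D spectral integral over the synthesis grid equals `targetSd^2`.
#' @return a [NoiseModel-class] object.
#' @examples
#' m <- noiseModel(amplitude = c(120, 100), peakFreq = c(0.03, 0.16))
#' f <- seq(0, 0.6, by = 0.002)
#' s <- evalNoiseModel(m, f)
#' @export
noiseModel <- function(amplitude, peakFreq, rise = 2, decay = 2,
                       targetSd = NA_real_) {
  n <- max(length(amplitude), length(peakFreq))
  cmp <- data.frame(
    amplitude = rep_len(as.numeric(amplitude), n),
    peakFreq = rep_len(as.numeric(peakFreq), n),
    rise = rep_len(as.numeric(rise), n),
    decay = rep_len(as.numeric(decay), n)
  )
  new("NoiseModel", components = cmp, targetSd = as.numeric(targetSd))
}

#' Evaluate a noise model on a frequency grid
#'
#' Sums the radial profiles of all components of `model` over a grid of
#' non-negative spatial frequencies. The `targetSd` rescaling is a property
#' of the synthesis grid and is therefore *not* applied here; see
#' [generateNoiseField()].
#'
#' @param model a [NoiseModel-class].
#' @param f numeric vector/array of spatial frequencies, mm^-1 (>= 0).
#' @return spectral densities with the shape of `f`, HU^2 mm^2.
#' @export
evalNoiseModel <- function(model, f) {
  stopifnot(is(model, "NoiseModel"))
  validObject(model)
  if (any(f < 0)) stop("negative spatial frequencies are not allowed")
  cmp <- model@components
  if (nrow(cmp) == 0L) stop("noise model has no components")
  out <- 0
  for (i in seq_len(nrow(cmp))) {
    x <- f / cmp$peakFreq[i]
    p <- cmp$rise[i]; q <- cmp$decay[i]
    if (p == 0) {
      s <- rep_len(cmp$amplitude[i], length(f))
      dim(s) <- dim(f)
    } else {
      # x^p is 0 at f = 0; the exponential is exp(p/q) * exp(-(p/q) x^q)
      s <- cmp$amplitude[i] * x^p * exp(-(p / q) * (x^q - 1))
    }
    out <- out + s
  }
  out
}

# Target 2-D spectrum on an FFT grid (wrap-around order), including the
# targetSd rescaling; DC is forced to zero so fields are exactly zero-mean.
noiseSpectrumGrid <- function(model, shape, spacing) {
  fu <- fftFreq(shape[2L], spacing)
  fv <- fftFreq(shape[1L], spacing)
  fr <- sqrt(outer(fv^2, fu^2, `+`))
  s <- evalNoiseModel(model, fr)
  s[1L, 1L] <- 0
  if (is.finite(model@targetSd)) {
    du <- 1 / (shape[2L] * spacing)
    dv <- 1 / (shape[1L] * spacing)
    v <- sum(s) * du * dv
    s <- if (v > 0) s * (model@targetSd^2 / v) else s
  }
  s
}

# Field synthesis with the caller's RNG stream (no seeding).
noiseFieldRaw <- function(shape, spacing, model) {
  cmp <- model@components
  flat <- nrow(cmp) == 1L && cmp$rise[1L] == 0
  if (flat) {
    # White component: frequency shaping is a constant filter, so sampling
    # i.i.d. Gaussians directly is exactly equivalent (and much cheaper).
    sd0 <- if (is.finite(model@targetSd)) model@targetSd
           else sqrt(cmp$amplitude[1L]) / spacing *
                sqrt((prod(shape) - 1) / prod(shape))
    f <- matrix(stats::rnorm(prod(shape), sd = sd0), shape[1L], shape[2L])
    return(f - mean(f))
  }
  s <- noiseSpectrumGrid(model, shape, spacing)
  w <- matrix(stats::rnorm(prod(shape)), shape[1L], shape[2L])
  g <- stats::fft(w) * sqrt(s) / spacing
  Re(stats::fft(g, inverse = TRUE)) / prod(shape)
}

#' Generate a stationary correlated noise field with a prescribed NPS
#'
#' Shapes white Gaussian noise in the frequency domain with the square root
#' of the radially symmetric target spectrum and inverse-transforms, giving
#' a zero-mean stationary Gaussian field whose expected periodogram equals
#' the target 2-D NPS. When `model@targetSd` is finite the spectrum is
#' rescaled so the theoretical field variance is `targetSd^2`.
#'
#' @param shape integer `c(rows, cols)` (>= 64 recommended for spectral
#'   fidelity).
#' @param spacing pixel spacing, mm (> 0).
#' @param model a [NoiseModel-class].
#' @param seed integer seed; the same `(shape, spacing, model, seed)` always
#'   returns the identical field. The caller's RNG state is untouched.
#' @return numeric matrix of HU deviations.
#' @export
generateNoiseField <- function(shape, spacing, model, seed) {
  if (length(shape) != 2L || any(shape < 2L)) stop("shape must be two sizes >= 2")
  if (spacing <= 0) stop("pixel spacing must be positive")
  shape <- as.integer(shape)
  withSeed(seed, noiseFieldRaw(shape, spacing, model))
}
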