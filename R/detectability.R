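#' Construct a detection task
#'
#' @param diameter lesion diameter, mm (default 10).
#' @param contrast lesion contrast, HU.
#' @param diameterAs `"fwhm"` (default) or `"2sigma"`: how the diameter of
#'   the Gaussian-profile lesion maps to its sigma.
#' @return a [TaskSpec-class].
#' @export
taskSpec <- function(diameter = 10, contrast, diameterAs = c("fwhm", "2sigma")) {
  new("TaskSpec", diameter = as.numeric(diameter),
      contrast = as.numeric(contrast), diameterAs = match.arg(diameterAs))
}

#' @rdname taskSpec
#' @param x a [TaskSpec-class].
#' @return `taskSigma`: the Gaussian sigma of the lesion profile, mm.
#' @export
taskSigma <- function(x) {
  stopifnot(is(x, "TaskSpec"))
  if (x@diameterAs == "fwhm") x@diameter / (2 * sqrt(2 * log(2)))
  else x@diameter / 2
}

#' Construct a viewing/display specification
#'
#' @param zoom display zoom factor (default 1.5).
#' @param distance viewing distance, mm (default 500).
#' @param eyeN1,eyeN2 eye-filter exponents (defaults 1.5 and 2).
#' @param eyePeak eye-filter peak, cycles/degree (default 4).
#' @return a [DisplaySpec-class].
#' @export
displaySpec <- function(zoom = 1.5, distance = 500,
                        eyeN1 = 1.5, eyeN2 = 2, eyePeak = 4) {
  new("DisplaySpec", zoom = as.numeric(zoom), distance = as.numeric(distance),
      eyeN1 = as.numeric(eyeN1), eyeN2 = as.numeric(eyeN2),
      eyePeak = as.numeric(eyePeak))
}

#' Frequency-domain task function of a circular Gaussian lesion
#'
#' The lesion `s(r) = C exp(-r^2 / 2 sigma^2)` has the radially symmetric
#' 2-D Fourier modulus
#' \deqn{W(f) = C \, 2\pi\sigma^2 \exp(-2\pi^2\sigma^2 f^2)}
#' with `W(0)` equal to the spatial integral of the signal.
#'
#' @param task a [TaskSpec-class].
#' @param f spatial frequencies, mm^-1 (>= 0).
#' @return task function values, HU mm^2.
#' @export
taskFunction <- function(task, f) {
  stopifnot(is(task, "TaskSpec"))
  if (any(f < 0)) stop("negative spatial frequencies are not allowed")
  sig <- taskSigma(task)
  task@contrast * 2 * pi * sig^2 * exp(-2 * pi^2 * sig^2 * f^2)
}

#' Angular conversion factor of a display geometry
#'
#' One cycle/degree at the eye corresponds to `zoom * distance * pi/180`
#' mm of image at the display plane, so `rho = f * zoom * distance *
#' pi/180` converts spatial frequency (mm^-1) to angular frequency
#' (cycles/degree).
#'
#' @param display a [DisplaySpec-class].
#' @return mm per cycles-per-degree unit.
#' @export
angularFactor <- function(display) {
  stopifnot(is(display, "DisplaySpec"))
  display@zoom * display@distance * pi / 180
}

#' Eye filter (visual response) on a spatial-frequency grid
#'
#' Band-pass model of human contrast sensitivity,
#' `E(rho) = rho^n1 exp(-c rho^n2)` with `c = n1 / (n2 * peak^n2)` so the
#' maximum lies at `peak` cycles/degree, normalized to a maximum value of
#' 1. Spatial frequencies are converted to angular frequencies via
#' [angularFactor()].
#'
#' @param f spatial frequencies, mm^-1 (>= 0).
#' @param display a [DisplaySpec-class].
#' @return unitless filter values in `[0, 1]`.
#' @export
eyeFilter <- function(f, display) {
  stopifnot(is(display, "DisplaySpec"))
  if (any(f < 0)) stop("negative spatial frequencies are not allowed")
  rho <- f * angularFactor(display)
  n1 <- display@eyeN1; n2 <- display@eyeN2; p <- display@eyePeak
  if (n1 == 0) return(rep(1, length(rho)))  # degenerate: no band-pass shaping
  cc <- n1 / (n2 * p^n2)
  emax <- p^n1 * exp(-n1 / n2)
  rho^n1 * exp(-cc * rho^n2) / emax
}

#' NPWE model-observer detectability index
#'
#' Computes the non-prewhitening-with-eye-filter detectability index
#' \deqn{d'^2 = \frac{\left[\iint W^2\,TTF^2\,E^2\,df\right]^2}
#'                    {\iint W^2\,TTF^2\,E^4\,NPS\,df}}
#' with both 2-D integrals evaluated as radial quadratures
#' `integral 2 pi f (.) df` over `[0, fmax]`. The TTF and NPS are linearly
#' interpolated onto the quadrature grid and clamped to their last value
#' beyond measured support. `ttf = NULL` uses an ideal system (TTF = 1);
#' `display = NULL` drops the eye filter (plain NPW observer).
#'
#' @param task a [TaskSpec-class].
#' @param nps an [NPSResult-class], or `list(freq =, nps =)` giving the
#'   radial NPS curve in HU^2 mm^2.
#' @param ttf a [TTFResult-class], `list(freq =, ttf =)`, or `NULL`.
#' @param display a [DisplaySpec-class] or `NULL`.
#' @param fmax upper integration limit, mm^-1 (default: the NPS Nyquist
#'   when available, else the last NPS frequency).
#' @param n quadrature points (default 4096).
#' @return list with `dprime`, the quadrature grid `freq`, and the
#'   integrand factors `task`, `ttf`, `eye`, `nps` on that grid.
#' @export
dprimeNpwe <- function(task, nps, ttf = NULL, display = NULL,
                       fmax = NULL, n = 4096L) {
  stopifnot(is(task, "TaskSpec"))
  if (is(nps, "NPSResult")) {
    npsF <- nps@freq; npsY <- nps@nps1d
    if (is.null(fmax)) fmax <- nps@nyquist
  } else {
    npsF <- nps$freq; npsY <- nps$nps
    if (is.null(fmax)) fmax <- max(npsF)
  }
  if (all(npsY == 0)) stop("NPS is identically zero: the observer noise integral is undefined")
  tf <- if (is.null(ttf)) NULL
        else if (is(ttf, "TTFResult")) list(freq = ttf@freq, ttf = ttf@ttf)
        else ttf
  f <- seq(0, fmax, length.out = as.integer(n))
  W <- taskFunction(task, f)
  Tt <- if (is.null(tf)) rep(1, length(f)) else interpClamp(tf$freq, tf$ttf, f)
  E <- if (is.null(display)) rep(1, length(f)) else eyeFilter(f, display)
  N <- interpClamp(npsF, npsY, f)
  num <- trapz(f, 2 * pi * f * W^2 * Tt^2 * E^2)
  den <- trapz(f, 2 * pi * f * W^2 * Tt^2 * E^4 * N)
  if (task@contrast == 0)   # zero-signal task: d' = 0 by definition
    return(list(dprime = 0, freq = f, task = W, ttf = Tt, eye = E, nps = N))
  if (den <= 0) stop("noise integral is zero: ideal-observer limit, d' undefined")
  list(dprime = num / sqrt(den), freq = f, task = W, ttf = Tt, eye = E, nps = N)
}
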