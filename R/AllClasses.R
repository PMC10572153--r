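#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' CTStack: a stack of axial CT slices in Hounsfield units
#'
#' The common currency of all estimators in the package: a 3-D voxel array
#' of Hounsfield units (HU) with uniform in-plane pixel spacing and slice
#' thickness. Voxels are stored `[row, col, slice]`; pixel centers sit at
#' `(index - 0.5) * pixelSpacing` millimetres from the array origin, so the
#' geometric center of a `N x N` slice is at `N/2 * pixelSpacing`.
#'
#' @slot voxels 3-D numeric array `[row, col, slice]`, HU.
#' @slot pixelSpacing in-plane pixel spacing, mm (isotropic).
#' @slot sliceThickness slice thickness, mm.
#' @slot metadata free-form label list (platform, keV, diameter, insert
#'   geometry written by the generator, ...).
#' @name CTStack-class
#' @aliases CTStack-class
#' @exportClass CTStack
setClass("CTStack",
  representation(
    voxels = "array",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    metadata = "list"
  ),
  prototype(sliceThickness = 1, metadata = list())
)

setValidity("CTStack", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3-D array [row, col, slice]")
  if (length(object@pixelSpacing) != 1L || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive number (mm)")
  if (length(object@sliceThickness) != 1L || object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be a single positive number (mm)")
  if (length(msg)) msg else TRUE
})

#' NoiseModel: parametric radial noise power spectrum
#'
#' A mixture of band-pass components describing a radially symmetric 2-D
#' noise power spectrum (NPS). Each component contributes
#' \deqn{S(f) = A \, (f/f_c)^p \exp\{-(p/q)\,[(f/f_c)^q - 1]\}}
#' which is non-negative, equals `A` at `f = fc`, and for `p > 0` attains
#' its maximum there. A component with `p = 0` is flat (white). Mixtures of
#' two components with well-separated `fc` produce the two-peak spectra
#' seen on split-filter CT virtual monoenergetic images.
#'
#' @slot components data.frame with columns `amplitude` (HU^2 mm^2),
#'   `peakFreq` (mm^-1), `rise` (p, unitless >= 0), `decay` (q, > 0).
#' @slot targetSd optional noise standard deviation (HU); when finite, the
#'   spectrum is rescaled at synthesis time so that its 2-D integral over
#'   the synthesis grid equals `targetSd^2`.
#' @name NoiseModel-class
#' @aliases NoiseModel-class
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(components = "data.frame", targetSd = "numeric"),
  prototype(targetSd = NA_real_)
)

setValidity("NoiseModel", function(object) {
  cmp <- object@components
  need <- c("amplitude", "peakFreq", "rise", "decay")
  if (!all(need %in% names(cmp)))
    return(sprintf("components must have columns %s", paste(need, collapse = ", ")))
  if (nrow(cmp) < 1L) return("at least one spectral component is required")
  if (any(cmp$amplitude < 0)) return("component amplitudes must be >= 0")
  if (any(cmp$peakFreq <= 0)) return("component peak frequencies must be > 0")
  if (any(cmp$rise < 0)) return("rise exponents p must be >= 0")
  if (any(cmp$decay <= 0)) return("decay exponents q must be > 0")
  if (length(object@targetSd) != 1L) return("targetSd must be length 1 (use NA to disable)")
  TRUE
})

#' PhantomSpec: geometry of a synthetic uniform phantom section
#'
#' Describes one cylindrical phantom section (uniform background disk in
#' air) with an optional circular contrast insert and Gaussian edge blur
#' standing in for the system PSF. Defaults reproduce a 380 mm field of
#' view on a 512 x 512 grid (0.7421875 mm/pixel) at 1 mm slice thickness.
#'
#' @slot sectionDiameter section diameter, mm (the study sections are 260,
#'   310 and 360 mm; any positive value is accepted for small test scenes).
#' @slot backgroundHU HU of the section material.
#' @slot insert `NULL`, or `list(center = c(x, y) mm, diameter = mm,
#'   contrast = HU)` relative to the array origin.
#' @slot edgeBlurSigma isotropic Gaussian blur sigma, mm (>= 0).
#' @slot nSlices number of slices.
#' @slot matrixSize integer `c(rows, cols)`.
#' @slot pixelSpacing mm per pixel.
#' @slot sliceThickness mm.
#' @slot seed integer RNG seed for the per-slice noise fields.
#' @name PhantomSpec-class
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    sectionDiameter = "numeric",
    backgroundHU = "numeric",
    insert = "listOrNULL",
    edgeBlurSigma = "numeric",
    nSlices = "integer",
    matrixSize = "integer",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@sectionDiameter <= 0) msg <- c(msg, "sectionDiameter must be > 0")
  if (object@pixelSpacing <= 0) msg <- c(msg, "pixelSpacing must be > 0")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (object@edgeBlurSigma < 0) msg <- c(msg, "edgeBlurSigma must be >= 0")
  if (length(object@matrixSize) != 2L || any(object@matrixSize < 16L))
    msg <- c(msg, "matrixSize must be two integers >= 16")
  ins <- object@insert
  if (!is.null(ins)) {
    if (!all(c("center", "diameter", "contrast") %in% names(ins)))
      msg <- c(msg, "insert needs center, diameter, contrast")
    else {
      ctr <- c(object@matrixSize[2L], object@matrixSize[1L]) / 2 * object@pixelSpacing
      d <- sqrt(sum((ins$center - ctr)^2))
      if (d + ins$diameter / 2 > object@sectionDiameter / 2)
        msg <- c(msg, "insert must lie fully inside the phantom section")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RoiLayout: homogeneous-region ROI placement for NPS estimation
#'
#' @slot roiSize square ROI side, pixels.
#' @slot centers `n x 2` matrix of ROI centers, pixel units `(row, col)`,
#'   1-based.
#' @slot slices integer vector of slice indices to use.
#' @name RoiLayout-class
#' @aliases RoiLayout-class
#' @exportClass RoiLayout
setClass("RoiLayout",
  representation(roiSize = "integer", centers = "matrix", slices = "integer")
)

setValidity("RoiLayout", function(object) {
  msg <- character()
  if (object@roiSize < 8L) msg <- c(msg, "roiSize must be >= 8 pixels")
  if (ncol(object@centers) != 2L || nrow(object@centers) < 1L)
    msg <- c(msg, "centers must be an n x 2 matrix (row, col)")
  if (length(object@slices) < 1L || any(object@slices < 1L))
    msg <- c(msg, "slices must be positive indices")
  if (length(msg)) msg else TRUE
})

#' NPSResult: estimated noise power spectrum and scalar noise metrics
#'
#' Two 1-D curves are maintained on purpose. The radial average of the 2-D
#' NPS (`nps1d`, HU^2 mm^2) is the curve on which peaks and the average
#' spatial frequency are read. The angular-integrated curve (`npsAngular`,
#' the per-ring integral divided by the bin width, HU^2 mm) carries the
#' 2*pi*f Jacobian so that its integral over frequency equals the full 2-D
#' integral of the NPS; the square root of that area is the noise
#' magnitude in HU (Parseval).
#'
#' @slot nps2d DC-centered 2-D NPS, HU^2 mm^2.
#' @slot freqU,freqV frequency axes of `nps2d`, mm^-1 (ascending).
#' @slot freq radial bin centers up to the Nyquist frequency, mm^-1.
#' @slot nps1d radial-average NPS at `freq`, HU^2 mm^2.
#' @slot nnps1d `nps1d` normalized to unit area.
#' @slot freqFull radial bin centers up to the grid corner frequency.
#' @slot npsAngular angular-integrated curve at `freqFull`, HU^2 mm.
#' @slot df radial frequency bin width, mm^-1.
#' @slot nyquist Nyquist frequency `1/(2 * spacing)`, mm^-1.
#' @slot noiseMagnitude sqrt of the NPS area, HU.
#' @slot fav average spatial frequency of `nps1d`, mm^-1 (NA if undefined).
#' @slot peaks data.frame `(fpeak, magnitude, prominence)`, at most 2 rows,
#'   ordered by magnitude (largest first).
#' @slot nBlocks number of ROI blocks averaged.
#' @slot pixelSpacing mm.
#' @name NPSResult-class
#' @aliases NPSResult-class
#' @exportClass NPSResult
setClass("NPSResult",
  representation(
    nps2d = "matrix", freqU = "numeric", freqV = "numeric",
    freq = "numeric", nps1d = "numeric", nnps1d = "numeric",
    freqFull = "numeric", npsAngular = "numeric",
    df = "numeric", nyquist = "numeric",
    noiseMagnitude = "numeric", fav = "numeric", peaks = "data.frame",
    nBlocks = "integer", pixelSpacing = "numeric"
  )
)

setValidity("NPSResult", function(object) {
  msg <- character()
  if (any(object@nps2d < -1e-9)) msg <- c(msg, "nps2d must be non-negative")
  if (length(object@freqU) != ncol(object@nps2d) ||
      length(object@freqV) != nrow(object@nps2d))
    msg <- c(msg, "frequency axes must match nps2d dimensions")
  if (length(object@nps1d) != length(object@freq))
    msg <- c(msg, "nps1d and freq must have equal length")
  if (length(msg)) msg else TRUE
})

#' EdgeProfile: radially binned edge spread function of a circular insert
#'
#' @slot binCenters radial distance from the insert center, mm
#'   (strictly increasing, uniform).
#' @slot esf per-bin mean HU.
#' @slot counts samples pooled per bin (across all slices).
#' @slot contrast inner plateau minus outer plateau, HU (signed).
#' @slot center subpixel insert center, mm `(x, y)`.
#' @slot binWidth mm.
#' @slot plateaus list with `inner` and `outer` plateau means (HU) and the
#'   radial windows they were read from.
#' @name EdgeProfile-class
#' @aliases EdgeProfile-class
#' @exportClass EdgeProfile
setClass("EdgeProfile",
  representation(
    binCenters = "numeric", esf = "numeric", counts = "integer",
    contrast = "numeric", center = "numeric", binWidth = "numeric",
    plateaus = "list"
  )
)

setValidity("EdgeProfile", function(object) {
  msg <- character()
  if (length(object@esf) != length(object@binCenters))
    msg <- c(msg, "esf and binCenters must have equal length")
  if (length(object@binCenters) > 1L) {
    d <- diff(object@binCenters)
    if (any(d <= 0) || diff(range(d)) > 1e-8 * mean(d))
      msg <- c(msg, "binCenters must be strictly increasing and uniform")
  }
  if (length(msg)) msg else TRUE
})

#' TTFResult: task-based transfer function of a circular insert
#'
#' @slot freq spatial frequency, mm^-1.
#' @slot ttf normalized transfer values (`ttf[freq == 0] == 1`).
#' @slot f50 frequency of the first downward 50% crossing, mm^-1
#'   (NA when the curve never crosses 0.5; `ttfF50()` then signals an error).
#' @slot lsf data.frame `(r, lsf, window)`: the finite-difference line
#'   spread function over radius and the Hann taper applied before the
#'   Fourier transform.
#' @slot contrast edge contrast, HU (signed).
#' @name TTFResult-class
#' @aliases TTFResult-class
#' @exportClass TTFResult
setClass("TTFResult",
  representation(
    freq = "numeric", ttf = "numeric", f50 = "numeric",
    lsf = "data.frame", contrast = "numeric"
  )
)

setValidity("TTFResult", function(object) {
  msg <- character()
  if (length(object@ttf) != length(object@freq))
    msg <- c(msg, "ttf and freq must have equal length")
  if (length(object@ttf) && abs(object@ttf[1L] - 1) > 1e-6)
    msg <- c(msg, "ttf must be normalized to 1 at zero frequency")
  if (length(msg)) msg else TRUE
})

#' TaskSpec: circular Gaussian-profile detection task
#'
#' The signal to be detected is circular with a Gaussian radial contrast
#' profile; its "diameter" is interpreted as the full width at half
#' maximum by default (`sigma = diameter / (2 sqrt(2 log 2))`), with a
#' `"2sigma"` reading available.
#'
#' @slot diameter lesion diameter, mm.
#' @slot contrast lesion contrast, HU.
#' @slot diameterAs `"fwhm"` (default) or `"2sigma"`.
#' @name TaskSpec-class
#' @aliases TaskSpec-class
#' @exportClass TaskSpec
setClass("TaskSpec",
  representation(diameter = "numeric", contrast = "numeric", diameterAs = "character"),
  prototype(diameter = 10, diameterAs = "fwhm")
)

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (object@diameter <= 0) msg <- c(msg, "diameter must be > 0")
  if (length(object@contrast) != 1L || object@contrast < 0)
    msg <- c(msg, "contrast must be a single value >= 0")
  if (!object@diameterAs %in% c("fwhm", "2sigma"))
    msg <- c(msg, 'diameterAs must be "fwhm" or "2sigma"')
  if (length(msg)) msg else TRUE
})

#' DisplaySpec: viewing geometry and eye filter for the NPWE observer
#'
#' Spatial frequencies f (mm^-1) are converted to angular frequencies rho
#' (cycles/degree) at the display via `rho = f * zoom * distance * pi/180`.
#' The eye filter is `E(rho) = rho^n1 * exp(-c * rho^n2)` with `c` fixed so
#' the maximum value 1 is attained at `peakFreq` cycles/degree.
#'
#' @slot zoom display zoom factor (unitless).
#' @slot distance viewing distance, mm.
#' @slot eyeN1,eyeN2 eye-filter exponents.
#' @slot eyePeak eye-filter peak angular frequency, cycles/degree.
#' @name DisplaySpec-class
#' @aliases DisplaySpec-class
#' @exportClass DisplaySpec
setClass("DisplaySpec",
  representation(
    zoom = "numeric", distance = "numeric",
    eyeN1 = "numeric", eyeN2 = "numeric", eyePeak = "numeric"
  ),
  prototype(zoom = 1.5, distance = 500, eyeN1 = 1.5, eyeN2 = 2, eyePeak = 4)
)

setValidity("DisplaySpec", function(object) {
  msg <- character()
  if (object@zoom <= 0) msg <- c(msg, "zoom must be > 0")
  if (object@distance <= 0) msg <- c(msg, "distance must be > 0")
  if (object@eyeN1 < 0 || object@eyeN2 <= 0 || object@eyePeak <= 0)
    msg <- c(msg, "eye filter needs n1 >= 0, n2 > 0, peakFreq > 0")
  if (length(msg)) msg else TRUE
})

#' StudyConfig: declarative description of a phantom study
#'
#' One row of `grid` per (dataset, diameter, keV) combination, carrying the
#' generator parameters for that combination; shared acquisition geometry
#' and observer settings live in the scalar slots.
#'
#' @slot grid data.frame with columns `dataset`, `diameter_cm`, `kev`,
#'   `contrast`, `targetSd`, `blurSigma`, `lowAmp`, `highAmp`, `fcLow`,
#'   `fcHigh`.
#' @slot nAcq repeated acquisitions pooled per combination.
#' @slot slicesPerAcqNps,slicesPerAcqTtf slices contributed per acquisition
#'   to the NPS and TTF estimates.
#' @slot matrixSize,pixelSpacing,sliceThickness,backgroundHU,insertDiameter
#'   shared acquisition geometry.
#' @slot task TaskSpec (its per-combination contrast is taken from `grid`).
#' @slot display DisplaySpec for the NPWE observer.
#' @slot seed base RNG seed.
#' @name StudyConfig-class
#' @aliases StudyConfig-class
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    grid = "data.frame",
    nAcq = "integer",
    slicesPerAcqNps = "integer",
    slicesPerAcqTtf = "integer",
    matrixSize = "integer",
    pixelSpacing = "numeric",
    sliceThickness = "numeric",
    backgroundHU = "numeric",
    insertDiameter = "numeric",
    task = "TaskSpec",
    display = "DisplaySpec",
    seed = "integer"
  )
)

setValidity("StudyConfig", function(object) {
  need <- c("dataset", "diameter_cm", "kev", "contrast", "targetSd",
            "blurSigma", "lowAmp", "highAmp", "fcLow", "fcHigh")
  if (!all(need %in% names(object@grid)))
    return(sprintf("grid must have columns %s", paste(need, collapse = ", ")))
  key <- with(object@grid, paste(dataset, diameter_cm, kev))
  if (anyDuplicated(key))
    return("each (dataset, diameter, keV) combination must appear exactly once")
  if (object@nAcq < 1L) return("nAcq must be >= 1")
  TRUE
})
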