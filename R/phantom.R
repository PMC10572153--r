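#' Describe a synthetic phantom section
#'
#' Convenience constructor for [PhantomSpec-class]. Defaults reproduce the
#' acquisition geometry used throughout the package: a 380 mm field of view
#' on a 512 x 512 matrix (0.7421875 mm/pixel) at 1 mm slice thickness, with
#' the section centered in the field of view.
#'
#' @param sectionDiameter section diameter, mm.
#' @param backgroundHU HU of the section material (air outside is -1000).
#' @param insert `NULL` or `list(center = c(x, y) mm, diameter = mm,
#'   contrast = HU)`; use [centeredInsert()] to place it at the section
#'   center.
#' @param edgeBlurSigma Gaussian PSF sigma, mm.
#' @param nSlices number of slices.
#' @param matrixSize one or two integers (rows, cols).
#' @param pixelSpacing mm/pixel.
#' @param sliceThickness mm.
#' @param seed integer seed for the per-slice noise.
#' @return a validated [PhantomSpec-class].
#' @export
phantomSpec <- function(sectionDiameter, backgroundHU = 35, insert = NULL,
                        edgeBlurSigma = 0.5, nSlices = 1L,
                        matrixSize = 512L, pixelSpacing = 380 / 512,
                        sliceThickness = 1, seed = 1L) {
  if (length(matrixSize) == 1L) matrixSize <- c(matrixSize, matrixSize)
  new("PhantomSpec",
      sectionDiameter = as.numeric(sectionDiameter),
      backgroundHU = as.numeric(backgroundHU),
      insert = insert,
      edgeBlurSigma = as.numeric(edgeBlurSigma),
      nSlices = as.integer(nSlices),
      matrixSize = as.integer(matrixSize),
      pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness),
      seed = as.integer(seed))
}

#' @rdname phantomSpec
#' @param contrast insert contrast vs the background, HU.
#' @param diameter insert diameter, mm.
#' @param matrixSize,pixelSpacing as in `phantomSpec` (used to find the
#'   geometric center of the field of view).
#' @export
centeredInsert <- function(contrast, diameter = 25,
                           matrixSize = 512L, pixelSpacing = 380 / 512) {
  if (length(matrixSize) == 1L) matrixSize <- c(matrixSize, matrixSize)
  list(center = c(matrixSize[2L], matrixSize[1L]) / 2 * pixelSpacing,
       diameter = diameter, contrast = contrast)
}

# exp(-z) * I0(z): besselI with large scaled arguments is slow, so switch
# to the (very accurate) large-argument asymptotic series beyond z = 50.
i0scaled <- function(z) {
  out <- numeric(length(z))
  big <- z > 50
  if (any(!big)) out[!big] <- besselI(z[!big], 0, expon.scaled = TRUE)
  if (any(big)) {
    zb <- z[big]
    out[big] <- (1 + 1 / (8 * zb) + 9 / (128 * zb^2) + 225 / (3072 * zb^3)) /
      sqrt(2 * pi * zb)
  }
  out
}

# Exact profile of a unit disk of radius R convolved with an isotropic
# Gaussian of width sigma, as a function of center distance r. This is the
# probability that an offset 2-D Gaussian lands inside the disk; evaluated
# by radial quadrature with scaled Bessel I0 for numerical stability at
# r/sigma >> 1. Returns values in [0, 1]; sigma = 0 gives the indicator.
blurredDiskProfile <- function(r, R, sigma) {
  if (sigma <= 0) return(as.numeric(r <= R))
  out <- numeric(length(r))
  lo <- r <= R - 6 * sigma
  hi <- r >= R + 6 * sigma
  out[lo] <- 1
  mid <- !(lo | hi)
  if (any(mid)) {
    rm_ <- r[mid]
    n <- 400L
    smax <- R
    smin <- max(0, min(rm_) - 8 * sigma)
    s <- seq(smin, smax, length.out = n)
    ds <- s[2L] - s[1L]
    # integrand: (s/sigma^2) exp(-(s-r)^2 / 2 sigma^2) I0~(r s / sigma^2)
    val <- vapply(rm_, function(ri) {
      z <- ri * s / sigma^2
      g <- (s / sigma^2) * exp(-(s - ri)^2 / (2 * sigma^2)) * i0scaled(z)
      w <- rep(1, n); w[c(1L, n)] <- 0.5
      sum(g * w) * ds
    }, numeric(1))
    out[mid] <- pmin(1, pmax(0, val))
  }
  out
}

# Noiseless HU scene of a phantom spec (matrix [row, col]).
phantomScene <- function(spec) {
  nr <- spec@matrixSize[1L]; nc <- spec@matrixSize[2L]
  dx <- spec@pixelSpacing
  xs <- (seq_len(nc) - 0.5) * dx
  ys <- (seq_len(nr) - 0.5) * dx
  cx <- nc / 2 * dx; cy <- nr / 2 * dx
  rr <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  scene <- -1000 + (spec@backgroundHU + 1000) *
    sceneCoverage(rr, spec@sectionDiameter / 2, spec@edgeBlurSigma)
  ins <- spec@insert
  if (!is.null(ins)) {
    ri <- sqrt(outer((ys - ins$center[2L])^2, (xs - ins$center[1L])^2, `+`))
    scene <- scene + ins$contrast *
      sceneCoverage(ri, ins$diameter / 2, spec@edgeBlurSigma)
  }
  scene
}

# Coverage lookup: tabulate the blurred-disk profile finely across the edge
# band and interpolate per pixel (the profile is smooth, so linear
# interpolation at sigma/50 steps is exact to ~1e-6).
sceneCoverage <- function(rr, R, sigma) {
  if (sigma <= 0) return(matrix(as.numeric(rr <= R), nrow(rr), ncol(rr)))
  band <- 6.5 * sigma
  grid <- seq(max(0, R - band), R + band, by = sigma / 50)
  prof <- blurredDiskProfile(grid, R, sigma)
  cov <- matrix(0, nrow(rr), ncol(rr))
  cov[rr <= R - band] <- 1
  mid <- rr > R - band & rr < R + band
  cov[mid] <- stats::approx(grid, prof, xout = rr[mid], rule = 2)$y
  cov
}

#' Generate a synthetic phantom image stack
#'
#' Renders the noiseless scene — uniform section disk at `backgroundHU` in
#' air (-1000 HU), plus an optional circular insert at `backgroundHU +
#' contrast` — convolved with an isotropic Gaussian of `edgeBlurSigma`
#' (computed as the exact circularly symmetric convolution, sampled at
#' pixel centers), then adds an independent stationary noise field per
#' slice drawn from `noise`. Metadata records the generator ground truth
#' (section/insert geometry, blur, labels) for downstream validation.
#'
#' @param spec a [PhantomSpec-class].
#' @param noise a [NoiseModel-class], or `NULL` for a noiseless stack.
#' @param label optional named list merged into the stack metadata
#'   (e.g. `list(platform = "A", kev = 40, diameter_cm = 26)`).
#' @return a [CTStack-class].
#' @examples
#' spec <- phantomSpec(60, nSlices = 2, matrixSize = 128L, pixelSpacing = 0.5,
#'                     insert = list(center = c(32, 32), diameter = 12,
#'                                   contrast = 500))
#' stk <- generatePhantomStack(spec, noiseModel(100, 0.15, targetSd = 20))
#' @export
generatePhantomStack <- function(spec, noise = NULL, label = list()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  if (!is.null(noise)) { stopifnot(is(noise, "NoiseModel")); validObject(noise) }
  scene <- phantomScene(spec)
  nr <- spec@matrixSize[1L]; nc <- spec@matrixSize[2L]
  vox <- array(0, c(nr, nc, spec@nSlices))
  noiseless <- is.null(noise) ||
    (is.finite(noise@targetSd) && noise@targetSd == 0)
  if (noiseless) {
    for (k in seq_len(spec@nSlices)) vox[, , k] <- scene
  } else {
    vox <- withSeed(spec@seed, {
      for (k in seq_len(spec@nSlices))
        vox[, , k] <- scene + noiseFieldRaw(c(nr, nc), spec@pixelSpacing, noise)
      vox
    })
  }
  md <- c(label, list(
    sectionDiameter = spec@sectionDiameter,
    backgroundHU = spec@backgroundHU,
    edgeBlurSigma = spec@edgeBlurSigma,
    insert = spec@insert,
    seed = spec@seed
  ))
  new("CTStack", voxels = vox, pixelSpacing = spec@pixelSpacing,
      sliceThickness = spec@sliceThickness, metadata = md)
}

#' Assemble a CTStack from raw voxels
#'
#' @param voxels 3-D array `[row, col, slice]` (a matrix is treated as one
#'   slice), HU.
#' @param pixelSpacing mm/pixel.
#' @param sliceThickness mm.
#' @param metadata free-form list.
#' @return a [CTStack-class].
#' @export
ctStack <- function(voxels, pixelSpacing, sliceThickness = 1, metadata = list()) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  new("CTStack", voxels = voxels, pixelSpacing = as.numeric(pixelSpacing),
      sliceThickness = as.numeric(sliceThickness), metadata = metadata)
}

#' Pool the slices of several stacks into one
#'
#' Emulates repeated acquisitions of the same phantom: stacks must share
#' matrix size and spacing; slices are concatenated in argument order.
#'
#' @param ... CTStack objects (or a single list of them).
#' @return a [CTStack-class] with the metadata of the first stack.
#' @export
poolStacks <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !is(xs[[1L]], "CTStack"))
    xs <- xs[[1L]]
  stopifnot(length(xs) >= 1L, all(vapply(xs, is, TRUE, "CTStack")))
  d1 <- dim(voxels(xs[[1L]]))[1:2]
  sp <- pixelSpacing(xs[[1L]])
  for (x in xs) {
    if (!identical(dim(voxels(x))[1:2], d1) ||
        abs(pixelSpacing(x) - sp) > 1e-9)
      stop("stacks must share matrix size and pixel spacing to be pooled")
  }
  all <- do.call(c, lapply(xs, function(x) as.vector(voxels(x))))
  n <- sum(vapply(xs, nSlices, 1L))
  new("CTStack", voxels = array(all, c(d1, n)), pixelSpacing = sp,
      sliceThickness = sliceThickness(xs[[1L]]), metadata = stackMetadata(xs[[1L]]))
}
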