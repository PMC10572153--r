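#' Construct an ROI layout
#'
#' @param roiSize square ROI side, pixels.
#' @param centers `n x 2` matrix of ROI centers `(row, col)`, pixel units.
#' @param slices slice indices to use.
#' @return a [RoiLayout-class].
#' @export
roiLayout <- function(roiSize, centers, slices) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2L, byrow = TRUE)
  new("RoiLayout", roiSize = as.integer(roiSize), centers = centers,
      slices = as.integer(slices))
}

#' Default ROI layout for a phantom section
#'
#' Four square ROIs at 90 degree intervals around the section center, at
#' half the section radius, with the conventional per-diameter sizes:
#' 80 pixels for the 26 cm section, 104 for 31 cm and 120 for 36 cm; 180
#' slices by default.
#'
#' @param diameterCm section diameter in cm (26, 31 or 36; other values
#'   take the nearest size).
#' @param matrixSize one or two integers (rows, cols) of the image grid.
#' @param pixelSpacing mm/pixel.
#' @param nSlicesUsed number of slices (default 180).
#' @param roiSize override the per-diameter ROI size, pixels.
#' @return a [RoiLayout-class].
#' @export
defaultRoiLayout <- function(diameterCm, matrixSize = 512L,
                             pixelSpacing = 380 / 512, nSlicesUsed = 180L,
                             roiSize = NULL) {
  if (length(matrixSize) == 1L) matrixSize <- c(matrixSize, matrixSize)
  if (is.null(roiSize)) {
    sizes <- c(`26` = 80L, `31` = 104L, `36` = 120L)
    roiSize <- sizes[[which.min(abs(c(26, 31, 36) - diameterCm))]]
  }
  rHalf <- diameterCm * 10 / 4 / pixelSpacing   # half the section radius, px
  c0 <- matrixSize / 2 + 0.5                    # pixel-index center
  ang <- c(0, 90, 180, 270) * pi / 180
  centers <- cbind(c0[1L] + rHalf * sin(ang), c0[2L] + rHalf * cos(ang))
  roiLayout(roiSize, centers, seq_len(nSlicesUsed))
}

#' Extract homogeneous-region ROI blocks from a stack
#'
#' Returns one `roiSize x roiSize` block per (slice, ROI) pair, slice-major
#' (all ROIs of slice 1, then slice 2, ...). ROIs must lie fully inside the
#' image; if the stack metadata declares an insert, ROIs overlapping it are
#' rejected by name.
#'
#' @param stack a [CTStack-class].
#' @param layout a [RoiLayout-class].
#' @return list of numeric matrices.
#' @export
extractRois <- function(stack, layout) {
  stopifnot(is(stack, "CTStack"), is(layout, "RoiLayout"))
  validObject(layout)
  d <- dim(voxels(stack))
  if (max(layout@slices) > d[3L])
    stop(sprintf("layout requests slice %d but the stack has %d slices",
                 max(layout@slices), d[3L]))
  sz <- layout@roiSize
  n <- nrow(layout@centers)
  starts <- matrix(0L, n, 2L)
  for (i in seq_len(n)) {
    r0 <- as.integer(floor(layout@centers[i, 1L] - sz / 2)) + 1L
    c0 <- as.integer(floor(layout@centers[i, 2L] - sz / 2)) + 1L
    if (r0 < 1L || c0 < 1L || r0 + sz - 1L > d[1L] || c0 + sz - 1L > d[2L])
      stop(sprintf("ROI %d (center %.1f, %.1f) extends outside the %d x %d image",
                   i, layout@centers[i, 1L], layout@centers[i, 2L], d[1L], d[2L]))
    starts[i, ] <- c(r0, c0)
  }
  ins <- stackMetadata(stack)$insert
  if (!is.null(ins)) {
    sp <- pixelSpacing(stack)
    # insert center in pixel-index units, with a 3-sigma blur margin
    icr <- ins$center[2L] / sp + 0.5
    icc <- ins$center[1L] / sp + 0.5
    irad <- ins$diameter / 2 / sp +
      3 * (stackMetadata(stack)$edgeBlurSigma %||% 0) / sp
    for (i in seq_len(n)) {
      rr <- c(starts[i, 1L], starts[i, 1L] + sz - 1L)
      cc <- c(starts[i, 2L], starts[i, 2L] + sz - 1L)
      dr <- max(rr[1L] - icr, icr - rr[2L], 0)
      dc <- max(cc[1L] - icc, icc - cc[2L], 0)
      if (sqrt(dr^2 + dc^2) < irad)
        stop(sprintf("ROI %d overlaps the declared insert", i))
    }
  }
  vox <- voxels(stack)
  out <- vector("list", length(layout@slices) * n)
  k <- 0L
  for (s in layout@slices) {
    for (i in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- vox[starts[i, 1L]:(starts[i, 1L] + sz - 1L),
                      starts[i, 2L]:(starts[i, 2L] + sz - 1L), s]
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cached design/pseudoinverse for degree-2 polynomial detrending.
detrendBasis <- function(nr, nc) {
  x <- rep(seq_len(nc), each = nr) / nc - 0.5
  y <- rep(seq_len(nr), times = nc) / nr - 0.5
  X <- cbind(1, x, y, x * y, x^2, y^2)
  list(X = X, P = solve(crossprod(X), t(X)))
}

#' Detrend an ROI block with a degree-2 polynomial surface
#'
#' Subtracts the least-squares 2-D polynomial of total degree 2 (six
#' coefficients) from the block, removing the DC level and any smooth
#' shading so the periodogram measures noise only.
#'
#' @param block numeric matrix, at least 8 x 8.
#' @param basis optional precomputed basis from repeated same-size calls
#'   (internal use).
#' @return residual matrix with zero mean.
#' @export
detrendRoi <- function(block, basis = NULL) {
  if (!is.matrix(block) || nrow(block) < 8L || ncol(block) < 8L)
    stop("block must be a matrix of at least 8 x 8 pixels")
  if (is.null(basis)) basis <- detrendBasis(nrow(block), ncol(block))
  beta <- basis$P %*% as.vector(block)
  res <- as.vector(block) - basis$X %*% beta
  matrix(res, nrow(block), ncol(block))
}

#' Averaged-periodogram 2-D noise power spectrum
#'
#' Estimates the 2-D NPS from detrended ROI blocks as
#' `NPS2D(u, v) = (dx * dy) / (Nx * Ny) * mean |DFT(block)|^2`,
#' DC-centered with physical frequency axes, then derives the radial
#' curves and scalar metrics (see [NPSResult-class], [npsMetrics()]). By
#' Parseval the integral of the 2-D NPS equals the mean block variance.
#'
#' @param blocks list of equal-size numeric matrices (already detrended;
#'   see [detrendRoi()]), or a single matrix.
#' @param spacing pixel spacing, mm.
#' @param peakProminence minimum prominence of a secondary NPS peak,
#'   as a fraction of the global maximum (default 0.05).
#' @return an [NPSResult-class].
#' @export
computeNps2d <- function(blocks, spacing, peakProminence = 0.05) {
  if (is.matrix(blocks)) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L, spacing > 0)
  d1 <- dim(blocks[[1L]])
  if (!all(vapply(blocks, function(b) identical(dim(b), d1), TRUE)))
    stop("all blocks must share one size")
  nr <- d1[1L]; nc <- d1[2L]
  acc <- matrix(0, nr, nc)
  for (b in blocks) acc <- acc + Mod(stats::fft(b))^2
  nps <- acc / length(blocks) * spacing^2 / (nr * nc)
  # double-precision residue of exactly noiseless blocks is not noise
  if (max(nps) <= 1e-18) nps[] <- 0
  # DC-center (fftshift) with ascending axes
  su <- order(fftFreq(nc, spacing))
  sv <- order(fftFreq(nr, spacing))
  res <- new("NPSResult",
             nps2d = nps[sv, su],
             freqU = fftFreq(nc, spacing)[su],
             freqV = fftFreq(nr, spacing)[sv],
             freq = numeric(), nps1d = numeric(), nnps1d = numeric(),
             freqFull = numeric(), npsAngular = numeric(),
             df = 1 / (max(nr, nc) * spacing), nyquist = 1 / (2 * spacing),
             noiseMagnitude = NA_real_, fav = NA_real_,
             peaks = data.frame(fpeak = numeric(), magnitude = numeric(),
                                prominence = numeric()),
             nBlocks = length(blocks), pixelSpacing = spacing)
  res <- addRadialProfiles(res)
  if (sum(res@nps2d) > 0) {
    m <- npsMetrics(res, peakProminence = peakProminence)
    res@noiseMagnitude <- m$noiseMagnitude
    res@fav <- m$fav
    res@peaks <- m$peaks
  }
  res
}

addRadialProfiles <- function(res) {
  du <- diff(res@freqU[1:2]); dv <- diff(res@freqV[1:2])
  fr <- sqrt(outer(res@freqV^2, res@freqU^2, `+`))
  df <- res@df
  bin <- as.integer(round(fr / df))
  kmax <- max(bin)
  sums <- vapply(0:kmax, function(k) sum(res@nps2d[bin == k]), numeric(1))
  cnts <- tabulate(bin + 1L, nbins = kmax + 1L)
  fullF <- (0:kmax) * df
  keep <- cnts > 0L
  # angular-integrated curve: exact per-ring integral / bin width, so that
  # sum(npsAngular) * df reproduces the full 2-D integral
  ang <- sums * du * dv / df
  nyq <- res@nyquist
  rad <- fullF <= nyq + 1e-12 & keep
  r1 <- sums[rad] / cnts[rad]
  res@freq <- fullF[rad]
  res@nps1d <- r1
  area <- sum(r1) * df
  res@nnps1d <- if (area > 0) r1 / area else r1
  res@freqFull <- fullF[keep]
  res@npsAngular <- ang[keep]
  res
}

#' Radial 1-D profiles of a 2-D NPS
#'
#' @param x an [NPSResult-class].
#' @return list with `freq` and the radial-average (`nps1d`), area-normalized
#'   (`nnps1d`) curves up to Nyquist, plus `freqFull`/`npsAngular` — the
#'   angular-integrated curve whose integral equals the 2-D NPS integral.
#' @export
radialProfiles <- function(x) {
  stopifnot(is(x, "NPSResult"))
  list(freq = x@freq, nps1d = x@nps1d, nnps1d = x@nnps1d,
       freqFull = x@freqFull, npsAngular = x@npsAngular, df = x@df)
}

# Prominence of the local maximum at index i of curve y: height above the
# higher of the two saddle minima separating it from higher terrain.
peakProminences <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    lmin <- h
    j <- i
    while (j > 1L && y[j] <= h) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    left <- if (y[j] > h) lmin else min(y[seq_len(i)])
    rmin <- h
    j <- i
    n <- length(y)
    while (j < n && y[j] <= h) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    right <- if (y[j] > h) rmin else min(y[i:n])
    h - max(left, right)
  }, numeric(1))
}

#' Scalar noise metrics of an NPS estimate
#'
#' The noise magnitude is the square root of the area under the
#' angular-integrated NPS curve (HU; by Parseval, the stationary noise
#' standard deviation). The average spatial frequency `f_av` is the
#' power-weighted mean frequency of the radial-average curve. Peaks are
#' local maxima of the radial-average curve, prominence-ranked: the global
#' maximum is always reported, and one secondary peak is added when its
#' prominence exceeds `peakProminence` times the global maximum.
#'
#' @param x an [NPSResult-class].
#' @param peakProminence secondary-peak prominence threshold (fraction of
#'   the global maximum).
#' @return list `(noiseMagnitude, fav, peaks)`.
#' @export
npsMetrics <- function(x, peakProminence = 0.05) {
  stopifnot(is(x, "NPSResult"))
  if (!length(x@nps1d) || sum(x@nps1d) <= 0)
    stop("NPS curve is identically zero: f_av and peaks are undefined")
  nm <- sqrt(sum(x@npsAngular) * x@df)
  fav <- sum(x@freq * x@nps1d) / sum(x@nps1d)
  y <- x@nps1d
  n <- length(y)
  peaks <- data.frame(fpeak = numeric(), magnitude = numeric(),
                      prominence = numeric())
  if (n >= 3L) {
    interior <- 2:(n - 1L)
    cand <- interior[y[interior] > y[interior - 1L] & y[interior] >= y[interior + 1L]]
    cand <- cand[x@freq[cand] > 0]
    if (length(cand)) {
      prom <- peakProminences(y, cand)
      ord <- order(y[cand], decreasing = TRUE)
      cand <- cand[ord]; prom <- prom[ord]
      take <- 1L
      if (length(cand) > 1L) {
        sec <- which(prom[-1L] >= peakProminence * y[cand[1L]])
        if (length(sec)) take <- c(1L, 1L + sec[1L])
      }
      peaks <- data.frame(fpeak = x@freq[cand[take]],
                          magnitude = y[cand[take]],
                          prominence = prom[take])
    }
  }
  list(noiseMagnitude = nm, fav = fav, peaks = peaks)
}

#' One-call NPS estimation from a stack
#'
#' Extracts ROI blocks ([extractRois()]), detrends each with a degree-2
#' polynomial ([detrendRoi()]) and averages their periodograms
#' ([computeNps2d()]).
#'
#' @param stack a [CTStack-class].
#' @param layout a [RoiLayout-class].
#' @param detrend subtract the polynomial trend first (default TRUE).
#' @param peakProminence see [npsMetrics()].
#' @return an [NPSResult-class].
#' @export
estimateNps <- function(stack, layout, detrend = TRUE, peakProminence = 0.05) {
  blocks <- extractRois(stack, layout)
  if (detrend) {
    basis <- detrendBasis(layout@roiSize, layout@roiSize)
    blocks <- lapply(blocks, detrendRoi, basis = basis)
  }
  computeNps2d(blocks, pixelSpacing(stack), peakProminence = peakProminence)
}
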