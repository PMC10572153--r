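#' Subpixel estimate of a circular insert's center
#'
#' Looks for the insert inside a circular search window: the inside plateau
#' is read near `approxCenter`, the outside plateau from the rim of the
#' window, pixels beyond the midpoint threshold are segmented, and their
#' intensity-weighted centroid (weights relative to the outside plateau) is
#' averaged across slices. Works for positive and negative contrast.
#'
#' @param stack a [CTStack-class].
#' @param approxCenter approximate insert center `c(x, y)`, mm.
#' @param searchRadius radius of the search window, mm (the insert must lie
#'   fully inside it).
#' @return numeric `c(x, y)` center in mm, subpixel.
#' @export
estimateCenter <- function(stack, approxCenter, searchRadius) {
  stopifnot(is(stack, "CTStack"), length(approxCenter) == 2L, searchRadius > 0)
  sp <- pixelSpacing(stack)
  vox <- voxels(stack)
  d <- dim(vox)
  xs <- (seq_len(d[2L]) - 0.5) * sp
  ys <- (seq_len(d[1L]) - 0.5) * sp
  rr <- sqrt(outer((ys - approxCenter[2L])^2, (xs - approxCenter[1L])^2, `+`))
  inWin <- rr <= searchRadius
  inCore <- rr <= 0.25 * searchRadius
  inRim <- rr >= 0.8 * searchRadius & inWin
  if (!any(inCore) || !any(inRim))
    stop("search window too small for the image grid")
  xmat <- matrix(xs, d[1L], d[2L], byrow = TRUE)
  ymat <- matrix(ys, d[1L], d[2L])
  cents <- matrix(NA_real_, nSlices(stack), 2L)
  for (k in seq_len(d[3L])) {
    sl <- vox[, , k]
    inside <- mean(sl[inCore])
    outside <- mean(sl[inRim])
    spread <- stats::sd(sl[inWin])
    if (!is.finite(spread) || abs(inside - outside) < spread)
      next   # no detectable plateau difference on this slice
    thr <- (inside + outside) / 2
    mask <- if (inside > outside) inWin & sl > thr else inWin & sl < thr
    if (!any(mask)) next
    w <- abs(sl[mask] - outside)
    cents[k, ] <- c(sum(w * xmat[mask]), sum(w * ymat[mask])) / sum(w)
  }
  ok <- stats::complete.cases(cents)
  if (!any(ok))
    stop("insert not found: no slice shows a plateau contrast above the noise")
  colMeans(cents[ok, , drop = FALSE])
}

#' Radial edge spread function of a circular insert
#'
#' Pools every pixel of every slice by its radial distance from the insert
#' center into uniform bins and averages, the first step of the circular
#' edge technique. Averaging across many slices suppresses image noise in
#' the profile. The edge contrast is read as the difference between the
#' inner and outer plateau means.
#'
#' @param stack a [CTStack-class].
#' @param center insert center `c(x, y)`, mm (see [estimateCenter()]).
#' @param range radial interval `c(lo, hi)` in mm; must straddle the insert
#'   radius with room for both plateaus.
#' @param binWidth radial bin width, mm (default 0.1 pixel).
#' @param plateauInner,plateauOuter fractions of `range` treated as the
#'   inside/outside plateau windows (defaults: inner 25%, outer 20%).
#' @param slices slice indices to pool (default: all).
#' @param fillEmpty interpolate empty radial bins from their neighbours
#'   instead of rejecting them (default FALSE; empty bins can only arise
#'   from the degenerate pixel-radius lattice of an exactly pixel-centered
#'   insert, so the pipeline wrapper [estimateTtf()] enables this).
#' @return an [EdgeProfile-class].
#' @export
radialEsf <- function(stack, center, range, binWidth = 0.1 * pixelSpacing(stack),
                      plateauInner = 0.25, plateauOuter = 0.2,
                      slices = seq_len(nSlices(stack)), fillEmpty = FALSE) {
  stopifnot(is(stack, "CTStack"), length(center) == 2L,
            length(range) == 2L, range[2L] > range[1L], binWidth > 0)
  sp <- pixelSpacing(stack)
  vox <- voxels(stack)
  d <- dim(vox)
  if (max(slices) > d[3L]) stop("requested slices exceed the stack")
  xs <- (seq_len(d[2L]) - 0.5) * sp
  ys <- (seq_len(d[1L]) - 0.5) * sp
  rr <- sqrt(outer((ys - center[2L])^2, (xs - center[1L])^2, `+`))
  sel <- rr >= range[1L] & rr < range[2L]
  if (!any(sel)) stop("no pixels fall inside the radial range")
  bin <- as.integer(floor((rr[sel] - range[1L]) / binWidth)) + 1L
  nb <- max(bin)
  cnt1 <- tabulate(bin, nbins = nb)
  grp <- which(cnt1 > 0L)
  sums <- numeric(nb)
  for (k in slices) {
    sl <- vox[, , k]
    sums[grp] <- sums[grp] + unname(rowsum(sl[sel], bin, reorder = TRUE)[, 1L])
  }
  counts <- cnt1 * length(slices)
  centers <- range[1L] + (seq_len(nb) - 0.5) * binWidth
  if (any(cnt1 == 0L)) {
    bad <- which(cnt1 == 0L)
    if (!fillEmpty)
      stop(sprintf("empty radial bin(s) inside the fit range (first at bin %d, r = %.3f mm); use a wider binWidth, a larger range start, or fillEmpty = TRUE",
                   bad[1L], centers[bad[1L]]))
  }
  esf <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  if (anyNA(esf)) {
    # pixel radii on an exact lattice can leave sub-0.1-pixel bins empty;
    # interpolate them from the neighbouring populated bins
    esf <- stats::approx(centers[!is.na(esf)], esf[!is.na(esf)],
                         xout = centers, rule = 2)$y
  }
  innerIdx <- centers <= range[1L] + plateauInner * diff(range)
  outerIdx <- centers >= range[2L] - plateauOuter * diff(range)
  inner <- sum(esf[innerIdx] * counts[innerIdx]) / sum(counts[innerIdx])
  outer <- sum(esf[outerIdx] * counts[outerIdx]) / sum(counts[outerIdx])
  new("EdgeProfile", binCenters = centers, esf = esf,
      counts = as.integer(counts), contrast = inner - outer,
      center = as.numeric(center), binWidth = binWidth,
      plateaus = list(inner = inner, outer = outer,
                      innerWindow = range(centers[innerIdx]),
                      outerWindow = range(centers[outerIdx])))
}

#' Task transfer function from a radial edge profile
#'
#' Differentiates the ESF with a centered finite difference to a line
#' spread function, applies a Hann taper centered on the LSF peak (by
#' default spanning the contiguous region where `|LSF|` exceeds 1% of its
#' peak) to suppress far-tail noise, and takes the modulus of the discrete
#' Fourier transform, normalized to 1 at zero frequency.
#'
#' @param profile an [EdgeProfile-class] with non-zero contrast.
#' @param windowThreshold fraction of the LSF peak delimiting the default
#'   taper support.
#' @param windowHalfWidth optional fixed taper half-width in mm, overriding
#'   the threshold rule.
#' @param freqMax highest frequency evaluated, mm^-1 (default: the smaller
#'   of 2 mm^-1 and the profile's radial Nyquist).
#' @param nFreq number of frequency samples.
#' @return a [TTFResult-class] (`f50` is `NA` when the curve never crosses
#'   0.5; [ttfF50()] then signals an error).
#' @export
ttfFromEsf <- function(profile, windowThreshold = 0.01, windowHalfWidth = NULL,
                       freqMax = NULL, nFreq = 401L) {
  stopifnot(is(profile, "EdgeProfile"))
  if (profile@contrast == 0)
    stop("edge contrast is zero: the TTF is undefined")
  r <- profile@binCenters
  e <- profile@esf
  n <- length(e)
  if (n < 5L) stop("too few ESF bins to differentiate")
  dr <- profile@binWidth
  lsf <- c(NA_real_, (e[3:n] - e[1:(n - 2L)]) / (2 * dr), NA_real_)
  lsf[1L] <- lsf[2L]; lsf[n] <- lsf[n - 1L]
  ipk <- which.max(abs(lsf))
  if (is.null(windowHalfWidth)) {
    thr <- windowThreshold * abs(lsf[ipk])
    lo <- ipk
    while (lo > 1L && abs(lsf[lo - 1L]) > thr) lo <- lo - 1L
    hi <- ipk
    while (hi < n && abs(lsf[hi + 1L]) > thr) hi <- hi + 1L
    hw <- max(ipk - lo, hi - ipk, 2L)
  } else {
    hw <- max(1L, as.integer(round(windowHalfWidth / dr)))
  }
  # flat over the detected LSF support, cosine-squared (Hann) taper of the
  # same width beyond: tapering only where the LSF is already below the
  # threshold leaves the transfer estimate unbiased while still killing
  # far-tail noise
  j <- seq_len(n)
  dist <- pmax(abs(j - ipk) - hw, 0) / hw
  win <- ifelse(dist >= 1, 0, cos(pi * dist / 2)^2)
  wl <- lsf * win
  nyq <- 1 / (2 * dr)
  if (is.null(freqMax)) freqMax <- min(2, nyq)
  freq <- seq(0, freqMax, length.out = nFreq)
  # explicit DTFT of the windowed LSF at the requested frequencies
  ph <- outer(freq, r, function(f, rr) -2 * pi * f * rr)
  spec <- complex(real = cos(ph) %*% wl, imaginary = sin(ph) %*% wl)
  mag <- Mod(spec)
  if (mag[1L] == 0) stop("windowed LSF integrates to zero: the TTF is undefined")
  ttf <- mag / mag[1L]
  f50 <- ttfCrossing(freq, ttf, 0.5)
  new("TTFResult", freq = freq, ttf = ttf, f50 = f50,
      lsf = data.frame(r = r, lsf = lsf, window = win),
      contrast = profile@contrast)
}

# first downward crossing of `level`, linearly interpolated; NA if none.
ttfCrossing <- function(freq, ttf, level) {
  below <- which(ttf < level)
  if (!length(below)) return(NA_real_)
  i <- below[1L]
  if (i == 1L) return(freq[1L])
  f0 <- freq[i - 1L]; f1 <- freq[i]
  t0 <- ttf[i - 1L]; t1 <- ttf[i]
  f0 + (level - t0) * (f1 - f0) / (t1 - t0)
}

#' Frequency at which the TTF falls to 50%
#'
#' @param x a [TTFResult-class].
#' @return `f50` in mm^-1.
#' @export
ttfF50 <- function(x) {
  stopifnot(is(x, "TTFResult"))
  if (!is.finite(x@f50))
    stop("the TTF never falls below 0.5 within the evaluated band")
  x@f50
}

#' One-call TTF estimation from a stack with a circular insert
#'
#' Locates the insert (from the stack's generator metadata when present,
#' otherwise via [estimateCenter()]), pools the radial ESF across `slices`,
#' and runs the circular-edge chain ESF -> LSF -> TTF.
#'
#' @param stack a [CTStack-class].
#' @param center optional insert center `c(x, y)` mm; default: refine the
#'   metadata insert center with [estimateCenter()].
#' @param insertDiameter insert diameter in mm (default from metadata).
#' @param slices slice indices to pool (default: all).
#' @param ... passed on to [ttfFromEsf()].
#' @return a [TTFResult-class].
#' @export
estimateTtf <- function(stack, center = NULL, insertDiameter = NULL,
                        slices = seq_len(nSlices(stack)), ...) {
  ins <- stackMetadata(stack)$insert
  if (is.null(insertDiameter)) {
    if (is.null(ins)) stop("insertDiameter is required when the stack metadata has no insert")
    insertDiameter <- ins$diameter
  }
  R <- insertDiameter / 2
  if (is.null(center)) {
    approx <- if (!is.null(ins)) ins$center else
      dim(voxels(stack))[c(2L, 1L)] / 2 * pixelSpacing(stack)
    center <- estimateCenter(stack, approx, searchRadius = 1.8 * R)
  }
  prof <- radialEsf(stack, center, range = c(0.5 * R, 1.8 * R), slices = slices,
                    fillEmpty = TRUE)
  ttfFromEsf(prof, ...)
}
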