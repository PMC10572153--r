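#' Accessors for ctiq objects
#'
#' Small accessor generics so user code never reaches into slots.
#'
#' @param x a ctiq object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("sliceThickness", function(x) standardGeneric("sliceThickness"))

#' @rdname accessors
#' @export
setGeneric("stackMetadata", function(x) standardGeneric("stackMetadata"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("noiseMagnitude", function(x) standardGeneric("noiseMagnitude"))

#' @rdname accessors
#' @export
setGeneric("averageFrequency", function(x) standardGeneric("averageFrequency"))

#' @rdname accessors
#' @export
setGeneric("npsPeaks", function(x) standardGeneric("npsPeaks"))

#' @export
#' @rdname accessors
setGeneric("edgeContrast", function(x) standardGeneric("edgeContrast"))

#' @rdname accessors
setMethod("voxels", "CTStack", function(x) x@voxels)

#' @rdname accessors
setMethod("pixelSpacing", "CTStack", function(x) x@pixelSpacing)

#' @rdname accessors
setMethod("sliceThickness", "CTStack", function(x) x@sliceThickness)

#' @rdname accessors
setMethod("stackMetadata", "CTStack", function(x) x@metadata)

#' @rdname accessors
setMethod("nSlices", "CTStack", function(x) dim(x@voxels)[3L])

#' @rdname accessors
setMethod("noiseMagnitude", "NPSResult", function(x) x@noiseMagnitude)

#' @rdname accessors
setMethod("averageFrequency", "NPSResult", function(x) x@fav)

#' @rdname accessors
setMethod("npsPeaks", "NPSResult", function(x) x@peaks)

#' @rdname accessors
setMethod("edgeContrast", "EdgeProfile", function(x) x@contrast)

#' @rdname accessors
setMethod("edgeContrast", "TTFResult", function(x) x@contrast)

setMethod("show", "CTStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTStack: %d slices of %d x %d pixels, %.4f mm/pixel, %.2f mm thick\n",
              d[3L], d[1L], d[2L], object@pixelSpacing, object@sliceThickness))
  md <- object@metadata
  if (length(md)) {
    keys <- names(md)[vapply(md, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
    if (length(keys))
      cat("  metadata:", paste(sprintf("%s=%s", keys, unlist(md[keys])), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel with %d component(s)\n", nrow(object@components)))
  print(object@components, row.names = FALSE)
  if (is.finite(object@targetSd))
    cat(sprintf("  rescaled to target SD %.3g HU\n", object@targetSd))
  invisible(object)
})

setMethod("show", "NPSResult", function(object) {
  cat(sprintf("NPSResult from %d ROI blocks (%d x %d, %.4f mm/pixel)\n",
              object@nBlocks, nrow(object@nps2d), ncol(object@nps2d),
              object@pixelSpacing))
  cat(sprintf("  noise magnitude %.3g HU, f_av %.4g mm^-1\n",
              object@noiseMagnitude, object@fav))
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks, row.names = FALSE)
  }
  invisible(object)
})

setMethod("show", "EdgeProfile", function(object) {
  cat(sprintf("EdgeProfile: %d radial bins of %.4g mm, contrast %.4g HU\n",
              length(object@esf), object@binWidth, object@contrast))
  invisible(object)
})

setMethod("show", "TTFResult", function(object) {
  cat(sprintf("TTFResult: %d frequencies up to %.3g mm^-1, f50 = %.4g mm^-1, contrast %.4g HU\n",
              length(object@freq), max(object@freq), object@f50, object@contrast))
  invisible(object)
})

setMethod("show", "TaskSpec", function(object) {
  cat(sprintf("TaskSpec: %.3g mm circular Gaussian task (%s), contrast %.4g HU\n",
              object@diameter, object@diameterAs, object@contrast))
  invisible(object)
})

setMethod("show", "DisplaySpec", function(object) {
  cat(sprintf("DisplaySpec: zoom %.3g, distance %.4g mm, eye filter (n1=%.3g, n2=%.3g, peak %.3g cyc/deg)\n",
              object@zoom, object@distance, object@eyeN1, object@eyeN2, object@eyePeak))
  invisible(object)
})

setMethod("show", "StudyConfig", function(object) {
  g <- object@grid
  cat(sprintf("StudyConfig: %d combinations (%d dataset(s) x %d diameter(s) x %d keV), nAcq = %d\n",
              nrow(g), length(unique(g$dataset)), length(unique(g$diameter_cm)),
              length(unique(g$kev)), object@nAcq))
  invisible(object)
})
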