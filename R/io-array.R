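# Portable compressed-array serialization: raw little-endian doubles
# (gzip) plus a JSON sidecar holding dimensions, spacing and metadata.

#' Write a CTStack as a compressed array with a JSON sidecar
#'
#' Stores the voxels as gzip-compressed little-endian doubles in
#' `<prefix>.bin.gz` and the dimensions, spacing, slice thickness and
#' scalar metadata in `<prefix>.json`. The round trip through
#' [readStackArray()] is exact.
#'
#' @param stack a [CTStack-class].
#' @param prefix output path prefix (directories are created).
#' @return invisibly, the two file paths.
#' @export
writeStackArray <- function(stack, prefix) {
  stopifnot(is(stack, "CTStack"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  binPath <- paste0(prefix, ".bin.gz")
  jsonPath <- paste0(prefix, ".json")
  con <- gzfile(binPath, "wb")
  writeBin(as.vector(voxels(stack)), con, size = 8, endian = "little")
  close(con)
  md <- stackMetadata(stack)
  simple <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
  side <- list(
    format = "ctiq-array-v1",
    dim = dim(voxels(stack)),
    order = "row,col,slice (column-major doubles)",
    pixel_spacing_mm = pixelSpacing(stack),
    slice_thickness_mm = sliceThickness(stack),
    metadata = simple
  )
  jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(binPath, jsonPath))
}

#' @rdname writeStackArray
#' @param prefix path prefix previously passed to `writeStackArray`.
#' @return `readStackArray`: the reconstructed [CTStack-class].
#' @export
readStackArray <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "ctiq-array-v1"))
    stop("not a ctiq array sidecar: ", paste0(prefix, ".json"))
  d <- as.integer(side$dim)
  con <- gzfile(paste0(prefix, ".bin.gz"), "rb")
  vox <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  close(con)
  if (length(vox) != prod(d)) stop("array payload does not match sidecar dimensions")
  md <- as.list(side$metadata)
  new("CTStack", voxels = array(vox, d),
      pixelSpacing = side$pixel_spacing_mm,
      sliceThickness = side$slice_thickness_mm,
      metadata = md)
}
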