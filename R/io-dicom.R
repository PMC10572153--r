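# Minimal single-frame CT DICOM series writer/reader (explicit VR, little
# endian). Covers exactly the tags the package needs to round-trip an HU
# stack with its geometry; not a general-purpose DICOM implementation.

.dcm <- list(
  explicitLE = "1.2.840.10008.1.2.1",
  ctStorage = "1.2.840.10008.5.1.4.1.1.2",
  implRoot = "1.2.826.0.1.3680043.9.7435"
)

u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

padStr <- function(s, nul = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2L) b <- c(b, if (nul) as.raw(0) else charToRaw(" "))
  b
}

dcmElement <- function(group, elem, vr, value) {
  body <- switch(vr,
    UI = padStr(value, nul = TRUE),
    CS = , LO = , DS = , IS = , SH = padStr(value),
    US = u16raw(value),
    UL = u32raw(value),
    OB = as.raw(value),
    OW = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    stop("unsupported VR ", vr))
  head <- c(u16raw(group), u16raw(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW"))
    c(head, raw(2), u32raw(length(body)), body)
  else
    c(head, u16raw(length(body)), body)
}

#' Write a CTStack as a DICOM series
#'
#' Writes one explicit-VR little-endian single-frame CT file per slice.
#' Voxels are stored as signed 16-bit integers with
#' `HU = stored * RescaleSlope + RescaleIntercept`; the default slope of
#' 0.1 HU quantizes the stack to 0.1 HU steps (a slope of 1 is chosen
#' automatically if 0.1 would overflow 16 bits), so reading the series back
#' returns the stack quantized to the slope. Scalar metadata entries are
#' encoded in the SeriesDescription as `key=value` pairs and restored on
#' read.
#'
#' @param stack a [CTStack-class].
#' @param dir output directory (created if needed).
#' @param slope rescale slope in HU per stored unit, or `NULL` (default)
#'   to pick 0.1 when it fits.
#' @return invisibly, the written file paths.
#' @export
writeDicomStack <- function(stack, dir, slope = NULL) {
  stopifnot(is(stack, "CTStack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- voxels(stack)
  intercept <- -1024
  if (is.null(slope)) {
    lim <- max(abs(range(vox) - intercept)) / 0.1
    slope <- if (lim < 32000) 0.1 else 1
  }
  md <- stackMetadata(stack)
  scal <- md[vapply(md, function(v) is.atomic(v) && length(v) == 1L &&
                      !is.na(v), TRUE)]
  desc <- paste(sprintf("%s=%s", names(scal), vapply(scal, format, "")),
                collapse = ";")
  if (desc == "") desc <- "ctiq"
  # deterministic UID derived from the label string, so identical stacks
  # always serialize identically
  seriesUID <- paste0(.dcm$implRoot, ".1.", sum(utf8ToInt(desc)) %% 99999L)
  studyUID <- paste0(seriesUID, ".0")
  d <- dim(vox)
  sp <- pixelSpacing(stack)
  files <- character(d[3L])
  for (k in seq_len(d[3L])) {
    stored <- round((vox[, , k] - intercept) / slope)
    storage.mode(stored) <- "integer"
    if (any(stored > 32767L | stored < -32768L))
      stop("stored values overflow 16 bits; pass a larger slope")
    sopUID <- paste0(seriesUID, ".", k)
    meta <- c(
      dcmElement(0x0002, 0x0001, "OB", c(0L, 1L)),
      dcmElement(0x0002, 0x0002, "UI", .dcm$ctStorage),
      dcmElement(0x0002, 0x0003, "UI", sopUID),
      dcmElement(0x0002, 0x0010, "UI", .dcm$explicitLE),
      dcmElement(0x0002, 0x0012, "UI", .dcm$implRoot)
    )
    z <- (k - 1) * sliceThickness(stack)
    # pixel data is written row-major per DICOM (row by row)
    px <- as.integer(t(stored))
    ds <- c(
      dcmElement(0x0008, 0x0016, "UI", .dcm$ctStorage),
      dcmElement(0x0008, 0x0018, "UI", sopUID),
      dcmElement(0x0008, 0x0060, "CS", "CT"),
      dcmElement(0x0008, 0x103E, "LO", desc),
      dcmElement(0x0020, 0x000D, "UI", studyUID),
      dcmElement(0x0020, 0x000E, "UI", seriesUID),
      dcmElement(0x0020, 0x0011, "IS", "1"),
      dcmElement(0x0020, 0x0013, "IS", as.character(k)),
      dcmElement(0x0020, 0x0032, "DS", sprintf("0\\0\\%.6f", z)),
      dcmElement(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
      dcmElement(0x0020, 0x1041, "DS", sprintf("%.6f", z)),
      dcmElement(0x0028, 0x0002, "US", 1L),
      dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcmElement(0x0028, 0x0010, "US", d[1L]),
      dcmElement(0x0028, 0x0011, "US", d[2L]),
      dcmElement(0x0028, 0x0030, "DS", sprintf("%.8f\\%.8f", sp, sp)),
      dcmElement(0x0018, 0x0050, "DS", sprintf("%.6f", sliceThickness(stack))),
      dcmElement(0x0028, 0x1052, "DS", sprintf("%.6f", intercept)),
      dcmElement(0x0028, 0x1053, "DS", sprintf("%.6f", slope)),
      dcmElement(0x0028, 0x0100, "US", 16L),
      dcmElement(0x0028, 0x0101, "US", 16L),
      dcmElement(0x0028, 0x0102, "US", 15L),
      dcmElement(0x0028, 0x0103, "US", 1L),
      dcmElement(0x7FE0, 0x0010, "OW", px)
    )
    files[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    con <- file(files[k], "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(dcmElement(0x0002, 0x0000, "UL", length(meta)), con)
    writeBin(meta, con)
    writeBin(ds, con)
    close(con)
  }
  invisible(files)
}

readU16 <- function(b, at) {
  readBin(b[at:(at + 1L)], "integer", size = 2, endian = "little", signed = FALSE)
}
readU32 <- function(b, at) {
  readBin(b[at:(at + 3L)], "integer", size = 4, endian = "little")
}

parseDicomFile <- function(path) {
  b <- readBin(path, raw(), file.size(path))
  if (length(b) < 140L || rawToChar(b[129:132]) != "DICM")
    stop(path, " is not a DICOM file (missing DICM marker)")
  at <- 133L
  longVR <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  n <- length(b)
  while (at + 7L <= n) {
    group <- readU16(b, at); elem <- readU16(b, at + 2L)
    vr <- rawToChar(b[(at + 4L):(at + 5L)])
    if (vr %in% longVR) {
      len <- readU32(b, at + 8L)
      at <- at + 12L
    } else {
      len <- readU16(b, at + 6L)
      at <- at + 8L
    }
    if (len < 0 || at + len - 1L > n)
      stop("corrupt element length in ", path)
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, bytes = if (len > 0) b[at:(at + len - 1L)] else raw(0))
    at <- at + len
  }
  out
}

dcmStr <- function(el) {
  if (is.null(el)) return(NULL)
  b <- el$bytes
  while (length(b) && b[length(b)] %in% as.raw(c(0L, 32L))) b <- b[-length(b)]
  rawToChar(b)
}
dcmNum <- function(el) {
  s <- dcmStr(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}
dcmU16 <- function(el) {
  readBin(el$bytes, "integer", size = 2, endian = "little", signed = FALSE)
}

#' Read a DICOM series into a CTStack
#'
#' Reads a directory of single-frame CT DICOM files (explicit VR little
#' endian) from one series: slices are sorted by position along the scan
#' axis, stored values are mapped to HU via RescaleSlope/RescaleIntercept,
#' and pixel spacing comes from the PixelSpacing tag. Mixed series
#' identifiers, missing rescale tags, or inconsistent geometry are
#' rejected.
#'
#' @param path directory containing `.dcm` files.
#' @return a [CTStack-class].
#' @export
readDicomSeries <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (!length(files)) stop("no .dcm files found under ", path)
  parsed <- lapply(files, parseDicomFile)
  need <- function(p, key, what, f) {
    el <- p[[key]]
    if (is.null(el)) stop("missing ", what, " tag (", key, ") in ", f)
    el
  }
  ts <- vapply(parsed, function(p) dcmStr(p[["0002,0010"]]) %||% "", "")
  if (any(ts != .dcm$explicitLE))
    stop("unsupported transfer syntax: only explicit VR little endian is handled")
  series <- vapply(seq_along(parsed), function(i)
    dcmStr(need(parsed[[i]], "0020,000E", "SeriesInstanceUID", files[i])), "")
  if (length(unique(series)) != 1L)
    stop("directory mixes ", length(unique(series)), " different series")
  zs <- vapply(seq_along(parsed), function(i) {
    ipp <- parsed[[i]][["0020,0032"]]
    if (!is.null(ipp)) dcmNum(ipp)[3L]
    else dcmNum(need(parsed[[i]], "0020,1041", "SliceLocation", files[i]))[1L]
  }, numeric(1))
  ord <- order(zs)
  parsed <- parsed[ord]; files <- files[ord]; zs <- zs[ord]
  geom <- function(p, f) {
    rows <- dcmU16(need(p, "0028,0010", "Rows", f))
    cols <- dcmU16(need(p, "0028,0011", "Columns", f))
    spac <- dcmNum(need(p, "0028,0030", "PixelSpacing", f))
    slope <- dcmNum(need(p, "0028,1053", "RescaleSlope", f))
    inter <- dcmNum(need(p, "0028,1052", "RescaleIntercept", f))
    c(rows, cols, spac[1L], spac[2L], slope, inter)
  }
  g1 <- geom(parsed[[1L]], files[1L])
  for (i in seq_along(parsed)[-1L]) {
    gi <- geom(parsed[[i]], files[i])
    if (!isTRUE(all.equal(g1, gi, tolerance = 1e-9)))
      stop("inconsistent geometry or rescale across files (", files[i], ")")
  }
  if (abs(g1[3L] - g1[4L]) > 1e-9)
    stop("anisotropic in-plane pixel spacing is not supported")
  nr <- g1[1L]; nc <- g1[2L]
  vox <- array(0, c(nr, nc, length(parsed)))
  for (i in seq_along(parsed)) {
    el <- need(parsed[[i]], "7FE0,0010", "PixelData", files[i])
    stored <- readBin(el$bytes, "integer", n = nr * nc, size = 2,
                      endian = "little", signed = TRUE)
    if (length(stored) != nr * nc)
      stop("pixel data size mismatch in ", files[i])
    vox[, , i] <- t(matrix(stored, nc, nr)) * g1[5L] + g1[6L]
  }
  thick <- dcmNum(parsed[[1L]][["0018,0050"]])
  if (is.null(thick)) thick <- if (length(zs) > 1L) diff(zs[1:2]) else 1
  md <- list()
  desc <- dcmStr(parsed[[1L]][["0008,103E"]])
  if (!is.null(desc) && nzchar(desc) && desc != "ctiq") {
    for (kv in strsplit(desc, ";")[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(parts) == 2L) {
        val <- suppressWarnings(as.numeric(parts[2L]))
        md[[parts[1L]]] <- if (is.na(val)) parts[2L] else val
      }
    }
  }
  new("CTStack", voxels = vox, pixelSpacing = g1[3L],
      sliceThickness = thick, metadata = md)
}
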