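# Minimal GeoTIFF I/O: uncompressed, single-band, strip-organised floating
# point rasters with ModelPixelScale/ModelTiepoint georeferencing and the
# GDAL_NODATA convention. Covers exactly the files this package reads and
# writes (CHMs, DTMs, pulse-density and derived grids); deliberately rejects
# multi-band, tiled or compressed layouts rather than guessing.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Read a single-band GeoTIFF
#'
#' Supports the layout this package writes: uncompressed strips, one sample
#' per pixel, 32- or 64-bit IEEE float or 8/16/32-bit integer samples,
#' georeferencing from ModelPixelScale + ModelTiepoint tags, nodata from the
#' GDAL_NODATA tag. Anything else (multi-band, tiles, compression) is
#' rejected with an explicit error.
#'
#' @param path file path.
#' @return a [height_raster] with nodata pixels as `NA`.
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  byte_order <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(byte_order, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", 1, 2, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1, 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    typ <- readBin(con, "integer", 1, 2, signed = FALSE, endian = endian)
    cnt <- readBin(con, "integer", 1, 4, endian = endian)
    raw4 <- readBin(con, "raw", 4)
    entries[[i]] <- list(tag = tag, type = typ, count = cnt, raw = raw4)
  }
  read_value <- function(e) {
    sz <- .tiff_type_size[[as.character(e$type)]]
    nbytes <- sz * e$count
    if (nbytes <= 4) {
      bytes <- e$raw[seq_len(nbytes)]
    } else {
      off <- readBin(e$raw, "integer", 1, 4, endian = endian)
      pos <- seek(con); seek(con, off)
      bytes <- readBin(con, "raw", nbytes)
      seek(con, pos)
    }
    switch(as.character(e$type),
      `2` = rawToChar(bytes[bytes != as.raw(0)]),
      `3` = readBin(bytes, "integer", e$count, 2, signed = FALSE, endian = endian),
      `4` = readBin(bytes, "integer", e$count, 4, endian = endian),
      `12` = readBin(bytes, "double", e$count, 8, endian = endian),
      `11` = readBin(bytes, "double", e$count, 4, endian = endian),
      readBin(bytes, "integer", e$count, sz, endian = endian))
  }
  tags <- list()
  for (e in entries) tags[[as.character(e$tag)]] <- read_value(e)
  g <- function(code, default = NULL)
    if (!is.null(tags[[as.character(code)]])) tags[[as.character(code)]] else default

  width <- g(256); height <- g(257)
  if (is.null(width) || is.null(height)) stop("TIFF missing image dimensions")
  spp <- g(277, 1L)
  if (spp != 1L) stop("multi-band TIFF not supported (", spp, " samples/pixel)")
  if (g(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (!is.null(g(322))) stop("tiled TIFF not supported")
  bps <- g(258, 1L)
  fmt <- g(339, 1L)  # 1 = unsigned int, 2 = signed int, 3 = IEEE float
  strip_off <- g(273); strip_cnt <- g(279)
  if (is.null(strip_off)) stop("TIFF missing strip offsets")
  rows_per_strip <- g(278, height)

  npix <- as.numeric(width) * height
  vec <- numeric(0)
  for (s in seq_along(strip_off)) {
    seek(con, strip_off[s])
    n_this <- strip_cnt[s] %/% (bps %/% 8L)
    vec <- c(vec, if (fmt == 3L)
      readBin(con, "double", n_this, bps %/% 8L, endian = endian)
    else
      readBin(con, "integer", n_this, bps %/% 8L,
              signed = !(fmt == 1L && bps < 32L), endian = endian))
  }
  if (length(vec) != npix) stop("TIFF pixel data truncated")
  m <- matrix(vec, nrow = height, ncol = width, byrow = TRUE)

  scale <- g(33550, c(1, 1, 0))
  tie <- g(33922, c(0, 0, 0, 0, height, 0))
  if (abs(scale[1] - scale[2]) > 1e-9)
    stop("non-square pixels not supported")
  nodata <- g(42113)
  nodata <- if (is.null(nodata)) -9999 else as.numeric(nodata)
  m[m == nodata] <- NA_real_
  # tiepoint maps raster position (I,J) to map (X,Y): upper-left corner
  xmin <- tie[4] - tie[1] * scale[1]
  ymax <- tie[5] + tie[2] * scale[2]
  height_raster(m, xmin = xmin, ymax = ymax, res = scale[1],
                crs = "local", nodata = nodata)
}

#' Write a raster as a single-band GeoTIFF
#'
#' Uncompressed, little-endian, one strip per image, IEEE float samples.
#' `NA` cells are written as the raster's nodata sentinel and flagged through
#' the GDAL_NODATA tag so other GIS software restores the mask.
#'
#' @param r a [height_raster].
#' @param path output path.
#' @param dtype `"float64"` (default; bit-exact round trips of double data)
#'   or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(r, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  stopifnot(inherits(r, "height_raster"))
  bps <- if (dtype == "float64") 64L else 32L
  m <- r$values
  m[is.na(m)] <- r$nodata
  vals <- as.numeric(t(m))  # TIFF is row-major
  nr <- nrow(r$values); nc <- ncol(r$values)
  nodata_str <- c(charToRaw(format(r$nodata, scientific = FALSE)), as.raw(0))
  if (length(nodata_str) %% 2L == 1L) nodata_str <- c(nodata_str, as.raw(0))
  geokeys <- as.integer(c(1, 1, 0, 1,  1025, 0, 1, 1))  # RasterPixelIsArea

  n_tags <- 15L
  ifd_off <- 8L
  ifd_size <- 2L + n_tags * 12L + 4L
  aux_off <- ifd_off + ifd_size
  off_scale <- aux_off                    # 3 doubles
  off_tie <- off_scale + 24L              # 6 doubles
  off_geokeys <- off_tie + 48L            # 8 shorts
  off_nodata <- off_geokeys + 16L
  off_pixels <- off_nodata + length(nodata_str)
  strip_bytes <- length(vals) * (bps %/% 8L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, 2, endian = "little")
  writeBin(ifd_off, con, 4, endian = "little")

  writeBin(n_tags, con, 2, endian = "little")
  entry <- function(tag, type, count, value, inline_short = FALSE) {
    writeBin(as.integer(tag), con, 2, endian = "little")
    writeBin(as.integer(type), con, 2, endian = "little")
    writeBin(as.integer(count), con, 4, endian = "little")
    if (inline_short) {
      writeBin(as.integer(value), con, 2, endian = "little")
      writeBin(0L, con, 2, endian = "little")
    } else writeBin(as.integer(value), con, 4, endian = "little")
  }
  entry(256, 4, 1, nc)                       # ImageWidth
  entry(257, 4, 1, nr)                       # ImageLength
  entry(258, 3, 1, bps, inline_short = TRUE) # BitsPerSample
  entry(259, 3, 1, 1, inline_short = TRUE)   # Compression = none
  entry(262, 3, 1, 1, inline_short = TRUE)   # Photometric = BlackIsZero
  entry(273, 4, 1, off_pixels)               # StripOffsets
  entry(277, 3, 1, 1, inline_short = TRUE)   # SamplesPerPixel
  entry(278, 4, 1, nr)                       # RowsPerStrip
  entry(279, 4, 1, strip_bytes)              # StripByteCounts
  entry(284, 3, 1, 1, inline_short = TRUE)   # PlanarConfiguration
  entry(339, 3, 1, 3, inline_short = TRUE)   # SampleFormat = IEEE float
  entry(33550, 12, 3, off_scale)             # ModelPixelScale
  entry(33922, 12, 6, off_tie)               # ModelTiepoint
  entry(34735, 3, 8, off_geokeys)            # GeoKeyDirectory
  entry(42113, 2, length(nodata_str), off_nodata)  # GDAL_NODATA
  writeBin(0L, con, 4, endian = "little")    # next IFD = none

  writeBin(c(r$res, r$res, 0), con, 8, endian = "little")
  writeBin(c(0, 0, 0, r$xmin, r$ymax, 0), con, 8, endian = "little")
  writeBin(geokeys, con, 2, endian = "little")
  writeBin(nodata_str, con)
  writeBin(vals, con, bps %/% 8L, endian = "little")
  invisible(path)
}
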