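#' Georeferenced single-band raster of heights or elevations
#'
#' Lightweight container used throughout the package for canopy height models
#' (CHMs), digital terrain models (DTMs), pulse-density surfaces and derived
#' grids. Values are stored as a numeric matrix whose first row is the
#' northernmost row of the map (the usual raster convention), with an
#' axis-aligned affine transform described by the origin of the upper-left
#' corner and a square pixel size.
#'
#' @param values numeric matrix; `NA` entries are treated as nodata.
#' @param xmin x map coordinate of the left edge of the first column (m).
#' @param ymax y map coordinate of the top edge of the first row (m).
#' @param res pixel size in map units (m); pixels are square.
#' @param crs free-text coordinate reference system label. The algorithms are
#'   CRS-agnostic and only require metric, axis-aligned coordinates.
#' @param nodata sentinel written to file for `NA` cells.
#'
#' @return An object of class `height_raster`.
#' @export
height_raster <- function(values, xmin = 0, ymax = nrow(values) * res,
                          res = 1, crs = "local", nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(res) || length(res) != 1L || !is.finite(res) || res <= 0)
    stop("`res` must be a single strictly positive number")
  structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         res = as.numeric(res), crs = as.character(crs),
         nodata = as.numeric(nodata)),
    class = "height_raster")
}

#' @export
print.height_raster <- function(x, ...) {
  cat("<height_raster> ", nrow(x$values), "x", ncol(x$values),
      " @ ", x$res, " m\n", sep = "")
  cat("  extent: x [", x$xmin, ", ", raster_xmax(x), "]  y [",
      raster_ymin(x), ", ", x$ymax, "]\n", sep = "")
  v <- x$values[is.finite(x$values)]
  if (length(v))
    cat("  values: ", signif(min(v), 6), " .. ", signif(max(v), 6),
        "  (", sum(is.na(x$values)), " nodata)\n", sep = "")
  invisible(x)
}

#' @export
dim.height_raster <- function(x) dim(x$values)

raster_xmax <- function(r) r$xmin + ncol(r$values) * r$res
raster_ymin <- function(r) r$ymax - nrow(r$values) * r$res

#' Map coordinates of pixel centres
#'
#' @param r a `height_raster`.
#' @param row,col pixel indices (1-based, row 1 = northernmost).
#' @return two-column matrix of x/y centre coordinates (m).
#' @export
rowcol_to_xy <- function(r, row, col) {
  cbind(x = r$xmin + (col - 0.5) * r$res,
        y = r$ymax - (row - 0.5) * r$res)
}

#' Pixel indices containing map coordinates
#'
#' Points on a pixel's left/top edge belong to that pixel; points on the
#' raster's outer right/bottom edge are clamped inward so that the full closed
#' extent is addressable.
#'
#' @inheritParams rowcol_to_xy
#' @param x,y map coordinates (m).
#' @return two-column integer matrix of row/col indices; `NA` outside extent.
#' @export
xy_to_rowcol <- function(r, x, y) {
  col <- floor((x - r$xmin) / r$res) + 1L
  row <- floor((r$ymax - y) / r$res) + 1L
  col[x == raster_xmax(r)] <- ncol(r$values)
  row[y == raster_ymin(r)] <- nrow(r$values)
  bad <- col < 1L | col > ncol(r$values) | row < 1L | row > nrow(r$values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Sample raster values at point locations
#'
#' @inheritParams xy_to_rowcol
#' @return numeric vector of pixel values (`NA` outside the raster).
#' @export
raster_extract <- function(r, x, y) {
  rc <- xy_to_rowcol(r, x, y)
  out <- rep(NA_real_, nrow(rc))
  ok <- !is.na(rc[, 1])
  out[ok] <- r$values[cbind(rc[ok, 1], rc[ok, 2])]
  out
}

#' Crop a raster to a window of pixel indices
#' @keywords internal
raster_crop_rc <- function(r, row0, row1, col0, col1) {
  height_raster(r$values[row0:row1, col0:col1, drop = FALSE],
                xmin = r$xmin + (col0 - 1L) * r$res,
                ymax = r$ymax - (row0 - 1L) * r$res,
                res = r$res, crs = r$crs, nodata = r$nodata)
}

#' Check grid compatibility of two rasters
#'
#' Two rasters are grid-compatible when they share the same pixel size and
#' their grids differ by a whole number of pixels, so that one can be laid on
#' the other without resampling. Used before differencing repeat-survey CHMs.
#'
#' @param a,b `height_raster` objects.
#' @param tol tolerance (m) for resolution and offset comparisons.
#' @return A list with elements `compatible` (logical), `same_extent`,
#'   `overlap` (named extent vector or `NULL`) and `offset_pixels`.
#' @export
check_alignment <- function(a, b, tol = 1e-6) {
  if (abs(a$res - b$res) > tol)
    stop("rasters have incompatible resolutions (", a$res, " vs ", b$res, " m)")
  off_x <- (b$xmin - a$xmin) / a$res
  off_y <- (b$ymax - a$ymax) / a$res
  int_off <- max(abs(off_x - round(off_x)), abs(off_y - round(off_y))) <= tol
  ox <- c(max(a$xmin, b$xmin), min(raster_xmax(a), raster_xmax(b)))
  oy <- c(max(raster_ymin(a), raster_ymin(b)), min(a$ymax, b$ymax))
  if (ox[1] >= ox[2] || oy[1] >= oy[2])
    stop("rasters do not overlap")
  list(compatible = int_off,
       same_extent = isTRUE(all.equal(c(a$xmin, a$ymax, dim(a$values)),
                                      c(b$xmin, b$ymax, dim(b$values)),
                                      tolerance = tol)),
       overlap = c(xmin = ox[1], xmax = ox[2], ymin = oy[1], ymax = oy[2]),
       offset_pixels = c(x = off_x, y = off_y))
}

#' Clip two grid-compatible rasters to their common extent
#'
#' Mirrors the survey-processing step of clipping the later CHM to the extent
#' of the earlier one so that only the overlapping area is analysed.
#'
#' @inheritParams check_alignment
#' @return list of the two clipped rasters, pixel-aligned and equally sized.
#' @export
clip_to_common <- function(a, b, tol = 1e-6) {
  al <- check_alignment(a, b, tol)
  if (!al$compatible) stop("rasters are not on a common grid")
  ov <- al$overlap
  clip1 <- function(r) {
    c0 <- round((ov["xmin"] - r$xmin) / r$res) + 1L
    c1 <- round((ov["xmax"] - r$xmin) / r$res)
    r0 <- round((r$ymax - ov["ymax"]) / r$res) + 1L
    r1 <- round((r$ymax - ov["ymin"]) / r$res)
    raster_crop_rc(r, r0, r1, c0, c1)
  }
  list(a = clip1(a), b = clip1(b))
}
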