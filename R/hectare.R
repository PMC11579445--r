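#' Tile a raster extent into 1-ha summary cells
#'
#' Lays a grid of square cells (100 m by default, i.e. 1 ha) over the raster,
#' anchored at the raster's upper-left origin. Cells that extend past the
#' raster edge are kept but flagged `edge = TRUE` with their true pixel
#' counts, so partial cells are never silently averaged as if complete. An
#' optional 0/1 mask raster (1 = excluded habitat) marks cells as `masked`
#' when more than half their valid pixels are excluded; masked cells are
#' dropped from all summaries.
#'
#' @param r a [height_raster] defining the extent and resolution.
#' @param cell_size_m cell edge length in m (default 100, one hectare).
#' @param mask optional [height_raster] of 0/1 (1 = exclude) on the same grid.
#' @return data.frame of class `hectare_grid`: one row per cell with pixel
#'   index ranges, centre coordinates, pixel counts and flags.
#' @export
hectare_grid <- function(r, cell_size_m = 100, mask = NULL) {
  stopifnot(inherits(r, "height_raster"))
  px <- cell_size_m / r$res
  if (abs(px - round(px)) > 1e-9)
    stop("cell_size_m must be a whole number of pixels")
  px <- as.integer(round(px))
  nr <- nrow(r$values); nc <- ncol(r$values)
  n_cr <- ceiling(nr / px); n_cc <- ceiling(nc / px)
  g <- expand.grid(cell_row = seq_len(n_cr), cell_col = seq_len(n_cc))
  g$row0 <- (g$cell_row - 1L) * px + 1L
  g$row1 <- pmin(g$cell_row * px, nr)
  g$col0 <- (g$cell_col - 1L) * px + 1L
  g$col1 <- pmin(g$cell_col * px, nc)
  g$n_pixels <- (g$row1 - g$row0 + 1L) * (g$col1 - g$col0 + 1L)
  g$edge <- g$n_pixels < px * px
  g$x_centre <- r$xmin + ((g$col0 + g$col1) / 2 - 0.5) * r$res
  g$y_centre <- r$ymax - ((g$row0 + g$row1) / 2 - 0.5) * r$res
  g$masked <- FALSE
  if (!is.null(mask)) {
    if (!isTRUE(all.equal(dim(mask$values), dim(r$values))))
      stop("mask must be on the same grid as the raster")
    for (i in seq_len(nrow(g))) {
      mv <- mask$values[g$row0[i]:g$row1[i], g$col0[i]:g$col1[i]]
      g$masked[i] <- mean(mv == 1, na.rm = TRUE) > 0.5
    }
  }
  g$cell_id <- seq_len(nrow(g))
  class(g) <- c("hectare_grid", "data.frame")
  attr(g, "cell_size_m") <- cell_size_m
  attr(g, "res") <- r$res
  attr(g, "xmin") <- r$xmin
  attr(g, "ymax") <- r$ymax
  g
}

cell_apply <- function(chm, cells, f) {
  stopifnot(inherits(cells, "hectare_grid"))
  vapply(seq_len(nrow(cells)), function(i) {
    v <- chm$values[cells$row0[i]:cells$row1[i], cells$col0[i]:cells$col1[i]]
    f(v[!is.na(v)])
  }, numeric(1))
}

#' Per-cell canopy cover
#'
#' Canopy cover is the percentage of valid CHM pixels strictly exceeding the
#' height threshold (default 4 m, matching the tree-inclusion rule of the
#' segmentation). Nodata pixels are excluded from the denominator; cells with
#' no valid pixel (or masked cells) get `NA` rather than zero.
#'
#' @param chm a CHM [height_raster].
#' @param cells a [hectare_grid] on the same raster.
#' @param threshold_m height threshold in m; strict `>`.
#' @return numeric vector, percent in \[0, 100\], one value per cell.
#' @export
canopy_cover <- function(chm, cells, threshold_m = 4) {
  if (threshold_m < 0) stop("threshold_m must be >= 0")
  out <- cell_apply(chm, cells, function(v)
    if (length(v) == 0) NA_real_ else 100 * mean(v > threshold_m))
  out[cells$masked] <- NA_real_
  out
}

#' Per-cell canopy volume
#'
#' Sum of pixel height times pixel area over each cell (m^3). A uniform 1-m
#' height gain over a full 1-ha cell therefore adds 10 000 m^3.
#'
#' @inheritParams canopy_cover
#' @return numeric vector of m^3 per cell.
#' @export
canopy_volume <- function(chm, cells) {
  pa <- chm$res^2
  out <- cell_apply(chm, cells, function(v)
    if (length(v) == 0) NA_real_ else sum(v) * pa)
  out[cells$masked] <- NA_real_
  out
}

#' Per-decade change in canopy cover and volume
#'
#' Differences the two surveys' per-cell canopy cover (at `threshold_m`) and
#' canopy volume and rescales the raw change linearly to a per-decade rate,
#' `rate = (t2 - t1) * 10 / interval_years`.
#'
#' @param chm_t1,chm_t2 aligned CHMs for the two surveys.
#' @param cells a [hectare_grid].
#' @param interval_years years between surveys.
#' @param threshold_m cover threshold in m.
#' @return data.frame with `cell_id`, `delta_cover` (percentage points per
#'   decade) and `delta_vol` (m^3 per decade).
#' @export
delta_metrics <- function(chm_t1, chm_t2, cells, interval_years,
                          threshold_m = 4) {
  al <- check_alignment(chm_t1, chm_t2)
  if (!al$same_extent)
    stop("CHMs must be clipped to a common extent first (see clip_to_common)")
  if (interval_years <= 0) stop("interval_years must be positive")
  k <- 10 / interval_years
  data.frame(
    cell_id = cells$cell_id,
    delta_cover = (canopy_cover(chm_t2, cells, threshold_m) -
                   canopy_cover(chm_t1, cells, threshold_m)) * k,
    delta_vol = (canopy_volume(chm_t2, cells) -
                 canopy_volume(chm_t1, cells)) * k)
}

#' Aggregate per-tree values onto the hectare grid
#'
#' Maps each tree to the cell containing its stem/apex location and applies a
#' summary function per cell, the mechanism behind the 1-ha landscape maps of
#' demographic rates.
#'
#' @param cells a [hectare_grid].
#' @param x,y tree coordinates (m).
#' @param value per-tree values to summarise.
#' @param fun summary function (default `mean`).
#' @return numeric vector, one summary per cell (`NA` for empty or masked).
#' @export
aggregate_trees <- function(cells, x, y, value, fun = mean) {
  size <- attr(cells, "cell_size_m")
  xmin <- attr(cells, "xmin")
  ymax <- attr(cells, "ymax")
  ccol <- floor((x - xmin) / size) + 1L
  crow <- floor((ymax - y) / size) + 1L
  key <- paste(crow, ccol)
  cell_key <- paste(cells$cell_row, cells$cell_col)
  out <- rep(NA_real_, nrow(cells))
  agg <- tapply(value, key, fun)
  idx <- match(names(agg), cell_key)
  ok <- !is.na(idx)
  out[idx[ok]] <- as.numeric(agg)[ok]
  out[cells$masked] <- NA_real_
  out
}
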