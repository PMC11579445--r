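#' Fill terrain depressions by priority flood
#'
#' Raises every cell to the lowest elevation from which water can reach the
#' raster edge, the standard prerequisite for flow routing. A small epsilon
#' gradient (default 1e-6 m per cell step) is imposed on filled flats so
#' routing never stalls on a perfectly level surface.
#'
#' @param dtm a terrain [height_raster] with no nodata holes.
#' @param eps monotone increment applied across filled flats (m).
#' @return the filled [height_raster].
#' @export
fill_sinks <- function(dtm, eps = 1e-6) {
  out <- dtm
  out$values <- cpp_priority_flood(dtm$values, eps)
  out
}

#' Slope of a terrain surface
#'
#' Slope tangent from central differences (one-sided at edges).
#'
#' @param dtm a terrain [height_raster].
#' @return matrix of `tan(beta)` values.
#' @export
terrain_slope <- function(dtm) {
  z <- dtm$values
  nr <- nrow(z); nc <- ncol(z)
  res <- dtm$res
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  if (nc >= 2) {
    gx[, 2:(nc - 1)] <- (z[, 3:nc, drop = FALSE] -
                           z[, 1:(nc - 2), drop = FALSE]) / (2 * res)
    gx[, 1] <- (z[, 2] - z[, 1]) / res
    gx[, nc] <- (z[, nc] - z[, nc - 1]) / res
  }
  if (nr >= 2) {
    gy[2:(nr - 1), ] <- (z[3:nr, , drop = FALSE] -
                           z[1:(nr - 2), , drop = FALSE]) / (2 * res)
    gy[1, ] <- (z[2, ] - z[1, ]) / res
    gy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / res
  }
  sqrt(gx^2 + gy^2)
}

.nbr_off <- cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1),
                  dc = c(0, 0, -1, 1, -1, 1, -1, 1))

#' Flow accumulation over a filled terrain
#'
#' Cells are processed in order of decreasing elevation (ties by cell index)
#' and each passes its accumulated area to its lower 8-neighbours. With
#' multiple-flow-direction routing (`"mfd"`) the flow is split across all
#' downslope neighbours with fractions proportional to slope; with `"d8"`
#' everything follows the single steepest descent (ties resolved by the
#' fixed neighbour order N, S, W, E, NW, NE, SW, SE). Accumulation of cells
#' with no lower in-domain neighbour leaves the domain; on a filled surface
#' these are boundary cells, and the total outflow equals the cell count.
#'
#' @param dtm a sink-filled terrain [height_raster].
#' @param routing `"mfd"` (default) or `"d8"`.
#' @return list with `acc` (matrix; number of cells draining through each
#'   cell, including itself) and `outflow_cells` (total accumulation that
#'   left the domain).
#' @export
flow_accumulation <- function(dtm, routing = c("mfd", "d8")) {
  routing <- match.arg(routing)
  z <- dtm$values
  if (anyNA(z)) stop("DTM contains nodata cells inside the domain")
  nr <- nrow(z); nc <- ncol(z)
  res <- dtm$res
  acc <- matrix(1, nr, nc)
  outflow <- 0
  dist <- sqrt(.nbr_off[, 1]^2 + .nbr_off[, 2]^2) * res
  ord <- order(-as.vector(z), seq_along(z))
  for (idx in ord) {
    r <- (idx - 1L) %% nr + 1L
    c <- (idx - 1L) %/% nr + 1L
    rr <- r + .nbr_off[, 1]; cc <- c + .nbr_off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    slope <- rep(-Inf, 8)
    nidx <- (cc - 1L) * nr + rr
    slope[ok] <- (z[idx] - z[nidx[ok]]) / dist[ok]
    down <- which(slope > 0)
    if (length(down) == 0) { outflow <- outflow + acc[idx]; next }
    if (routing == "d8") {
      j <- down[which.max(slope[down])]
      acc[nidx[j]] <- acc[nidx[j]] + acc[idx]
    } else {
      w <- slope[down] / sum(slope[down])
      acc[nidx[down]] <- acc[nidx[down]] + acc[idx] * w
    }
  }
  list(acc = acc, outflow_cells = outflow)
}

#' Topographic wetness index
#'
#' `TWI = ln(a / tan(beta))`, with specific catchment area
#' `a = accumulation * cell area / contour width` (contour width = cell
#' size) and slope floored at `min_slope` so flat cells stay finite. The
#' DTM is sink-filled first unless `fill = FALSE`.
#'
#' @param dtm a terrain [height_raster] (typically 5-m resolution).
#' @param routing flow routing passed to [flow_accumulation()].
#' @param min_slope floor for `tan(beta)` (default 0.001).
#' @param fill sink-fill before routing (default `TRUE`).
#' @return a [height_raster] of TWI values.
#' @export
compute_twi <- function(dtm, routing = c("mfd", "d8"), min_slope = 0.001,
                        fill = TRUE) {
  routing <- match.arg(routing)
  if (anyNA(dtm$values))
    stop("DTM contains nodata cells; crop or fill them before computing TWI")
  filled <- if (fill) fill_sinks(dtm) else dtm
  fa <- flow_accumulation(filled, routing)
  tanb <- pmax(terrain_slope(filled), min_slope)
  a <- fa$acc * dtm$res   # cells * res^2 / res
  out <- dtm
  out$values <- log(a / tanb)
  out
}

#' Neighbourhood canopy height around each crown
#'
#' Mean CHM height within a buffer (default 25 m) around each crown's
#' perimeter, a size-symmetric proxy of local stand basal area and hence of
#' neighbourhood competition. The buffer annulus is the set of pixels within
#' `buffer_m` of the crown but outside it; the focal crown's own pixels are
#' excluded unless `include_focal = TRUE`. Crowns whose buffer is clipped by
#' the raster edge are flagged.
#'
#' @param crowns a `crown_set` from [two_stage_segment()].
#' @param chm the CHM to average (normally the same survey's).
#' @param buffer_m buffer distance (m).
#' @param include_focal include the focal crown's own pixels in the mean.
#' @return data.frame with `id`, `neighbourhood_height` (m), `edge_clipped`.
#' @export
neighbourhood_height <- function(crowns, chm, buffer_m = 25,
                                 include_focal = FALSE) {
  stopifnot(inherits(crowns, "crown_set"))
  lab <- crowns$labels
  if (!identical(dim(lab), dim(chm$values)))
    stop("crown labels and CHM are on different grids")
  nr <- nrow(lab); nc <- ncol(lab)
  res <- chm$res
  bpx <- ceiling(buffer_m / res)
  idx <- which(lab > 0)
  if (length(idx) == 0)
    return(data.frame(id = integer(), neighbourhood_height = numeric(),
                      edge_clipped = logical()))
  lrow <- (idx - 1L) %% nr + 1L
  lcol <- (idx - 1L) %/% nr + 1L
  lv <- lab[idx]
  r0 <- tapply(lrow, lv, min); r1 <- tapply(lrow, lv, max)
  c0 <- tapply(lcol, lv, min); c1 <- tapply(lcol, lv, max)
  ids <- as.integer(names(r0))
  out <- data.frame(id = ids, neighbourhood_height = NA_real_,
                    edge_clipped = FALSE)
  for (k in seq_along(ids)) {
    wr0 <- r0[[k]] - bpx; wr1 <- r1[[k]] + bpx
    wc0 <- c0[[k]] - bpx; wc1 <- c1[[k]] + bpx
    out$edge_clipped[k] <- wr0 < 1 || wr1 > nr || wc0 < 1 || wc1 > nc
    wr0 <- max(1L, wr0); wr1 <- min(nr, wr1)
    wc0 <- max(1L, wc0); wc1 <- min(nc, wc1)
    sub <- lab[wr0:wr1, wc0:wc1, drop = FALSE]
    mask <- sub == ids[k]
    d <- sqrt(cpp_edt_sq(mask)) * res
    sel <- d <= buffer_m & (include_focal | d > 0)
    vals <- chm$values[wr0:wr1, wc0:wc1, drop = FALSE][sel]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) stop("empty buffer annulus for crown ", ids[k])
    out$neighbourhood_height[k] <- mean(vals)
  }
  out
}

#' Pulse-density difference at tree locations
#'
#' Samples the difference between the two surveys' pulse-density fields
#' (`t2 - t1`) at each tree position; swapping surveys flips the sign.
#'
#' @param pd_t1,pd_t2 aligned pulse-density rasters.
#' @param x,y tree coordinates (m).
#' @return numeric vector of pulses per m^2.
#' @export
pulse_density_difference <- function(pd_t1, pd_t2, x, y) {
  al <- check_alignment(pd_t1, pd_t2)
  if (!al$compatible) stop("pulse-density rasters are not on a common grid")
  v1 <- raster_extract(pd_t1, x, y)
  v2 <- raster_extract(pd_t2, x, y)
  if (anyNA(v1) || anyNA(v2))
    stop("tree location outside the pulse-density rasters")
  v2 - v1
}

#' Assemble the per-tree covariate table for the driver models
#'
#' Joins each tracked tree's first-survey size metric, topographic wetness
#' (sampled at the crown centroid), neighbourhood canopy height and
#' pulse-density difference onto the matched-tree table, producing the
#' input expected by [fit_gam()]. Ambiguous and unresolved trees are
#' retained in the table but carry their status so model fitting can drop
#' them.
#'
#' @param trees a `matched_trees` table (see [classify_fate()]).
#' @param crowns_t1 the first-survey `crown_set`.
#' @param chm_t1 the first-survey CHM (for neighbourhood height).
#' @param twi TWI raster from [compute_twi()].
#' @param pd_t1,pd_t2 pulse-density rasters.
#' @param buffer_m neighbourhood buffer (m).
#' @return the table with `size`, `twi`, `neigh`, `pd_diff` and a 0/1
#'   `died` column.
#' @export
tree_covariates <- function(trees, crowns_t1, chm_t1, twi, pd_t1, pd_t2,
                            buffer_m = 25) {
  trees$size <- size_metric(trees$H_t1, trees$CD_t1)
  trees$twi <- raster_extract(twi, trees$x, trees$y)
  nb <- neighbourhood_height(crowns_t1, chm_t1, buffer_m)
  trees$neigh <- nb$neighbourhood_height[match(trees$id_t1, nb$id)]
  trees$pd_diff <- pulse_density_difference(pd_t1, pd_t2, trees$x, trees$y)
  trees$died <- as.integer(trees$status == "dead_or_dieback")
  trees
}
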