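# Crown exports: attribute CSV and traced pixel-boundary polygons as GeoJSON.

#' Write crown attributes as CSV
#'
#' @param crowns a `crown_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crowns_csv <- function(crowns, path) {
  utils::write.csv(crowns$crowns, path, row.names = FALSE)
  invisible(path)
}

# Trace the pixel-boundary rings of one crown. Directed boundary edges keep
# the crown interior on the left; rings are closed by walking corner to
# corner, taking the sharpest left turn at corner-touching pixels so
# diagonally touching parts stay in separate rings. Returns a list of rings
# (closed coordinate matrices, map units); positive shoelace area = outer.
trace_rings <- function(mask, xmin, ymax, res) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) return(list())
  inm <- function(r, c) {
    ok <- r >= 1 & r <= nrow(mask) & c >= 1 & c <= ncol(mask)
    res <- logical(length(r))
    res[ok] <- mask[cbind(r[ok], c[ok])]
    res
  }
  # corners indexed (i,j), i in 0..nr, j in 0..nc; key = i * (nc+1) + j
  nc1 <- ncol(mask) + 1L
  key <- function(i, j) i * nc1 + j
  r <- px[, 1]; c <- px[, 2]
  south <- !inm(r + 1L, c); east <- !inm(r, c + 1L)
  north <- !inm(r - 1L, c); west <- !inm(r, c - 1L)
  # directed edges, interior on the left (map coords, y up):
  e <- rbind(
    if (any(south)) cbind(key(r[south], c[south] - 1L), key(r[south], c[south])),
    if (any(east))  cbind(key(r[east], c[east]), key(r[east] - 1L, c[east])),
    if (any(north)) cbind(key(r[north] - 1L, c[north]), key(r[north] - 1L, c[north] - 1L)),
    if (any(west))  cbind(key(r[west] - 1L, c[west] - 1L), key(r[west], c[west] - 1L)))
  used <- rep(FALSE, nrow(e))
  # outgoing edge lookup per corner
  out_idx <- split(seq_len(nrow(e)), e[, 1])
  corner_xy <- function(k) {
    i <- k %/% nc1; j <- k %% nc1
    c(xmin + j * res, ymax - i * res)
  }
  rings <- list()
  for (s in seq_len(nrow(e))) {
    if (used[s]) next
    path <- e[s, 1]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nxt_corner <- e[cur, 2]
      path <- c(path, nxt_corner)
      if (nxt_corner == path[1]) break
      cand <- out_idx[[as.character(nxt_corner)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break  # defensive; closed by construction
      if (length(cand) > 1) {
        # sharpest left turn relative to current direction
        dir_in <- corner_xy(e[cur, 2]) - corner_xy(e[cur, 1])
        angs <- vapply(cand, function(k) {
          dir_out <- corner_xy(e[k, 2]) - corner_xy(e[k, 1])
          atan2(dir_in[1] * dir_out[2] - dir_in[2] * dir_out[1],
                sum(dir_in * dir_out))
        }, numeric(1))
        cur <- cand[which.max(angs)]
      } else cur <- cand
    }
    xy <- t(vapply(path, corner_xy, numeric(2)))
    colnames(xy) <- c("x", "y")
    rings[[length(rings) + 1L]] <- xy
  }
  rings
}

shoelace <- function(xy) {
  n <- nrow(xy)
  sum(xy[-n, 1] * xy[-1, 2] - xy[-1, 1] * xy[-n, 2]) / 2
}

#' Exact pixel-boundary polygons of segmented crowns
#'
#' Traces each crown's pixel boundary in map coordinates. Polygon area
#' equals pixel count times pixel area exactly. Rings with positive
#' (counter-clockwise) area are outer boundaries; negative rings are holes.
#'
#' @param crowns a `crown_set`.
#' @return named list (by crown id) of lists of rings (closed two-column
#'   coordinate matrices).
#' @export
crown_polygons <- function(crowns) {
  stopifnot(inherits(crowns, "crown_set"))
  lab <- crowns$labels
  meta <- crowns$raster
  out <- lapply(crowns$crowns$id, function(id)
    trace_rings(lab == id, meta$xmin, meta$ymax, meta$res))
  names(out) <- crowns$crowns$id
  out
}

#' Write crowns as a GeoJSON FeatureCollection
#'
#' Each crown becomes a Polygon (outer ring plus any holes) with its
#' attribute row as properties.
#'
#' @param crowns a `crown_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_crowns_geojson <- function(crowns, path) {
  polys <- crown_polygons(crowns)
  feats <- lapply(seq_along(polys), function(i) {
    rings <- polys[[i]]
    areas <- vapply(rings, shoelace, numeric(1))
    ord <- order(-areas)   # outer ring(s) first
    coords <- lapply(rings[ord], function(xy)
      lapply(seq_len(nrow(xy)), function(j) c(xy[j, 1], xy[j, 2])))
    props <- as.list(crowns$crowns[i, , drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = props)
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
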