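label_raster <- function(cs) {
  height_raster(cs$labels, xmin = cs$raster$xmin, ymax = cs$raster$ymax,
                res = cs$raster$res, crs = cs$raster$crs)
}

#' Match crowns across two surveys by centroid containment
#'
#' A first-survey crown and a second-survey crown are candidate matches when
#' the t1 crown polygon contains the centroid of the t2 crown. Containment
#' is evaluated on the label grid (the pixel holding the centroid), which
#' makes boundary points deterministically exclusive. Any crown in either
#' survey that contains two or more centroids from the other survey signals
#' probable oversegmentation: every candidate pair involving such a crown is
#' removed and the t1 trees involved are marked ambiguous. The surviving
#' pairing is one-to-one.
#'
#' @param crowns_t1,crowns_t2 `crown_set` objects on the same grid.
#' @return list of class `crown_matching`: `pairs` (data.frame `id_t1`,
#'   `id_t2`), `ambiguous_t1` (ids), `unmatched_t1` (ids), `recruit_t2`
#'   (t2 ids matching no t1 crown; counted, never converted to rates).
#' @export
match_crowns <- function(crowns_t1, crowns_t2) {
  if (!identical(dim(crowns_t1$labels), dim(crowns_t2$labels)))
    stop("crown sets are on different grids")
  c1 <- crowns_t1$crowns; c2 <- crowns_t2$crowns
  l1 <- label_raster(crowns_t1); l2 <- label_raster(crowns_t2)
  in_t1 <- if (nrow(c2)) raster_extract(l1, c2$centroid_x, c2$centroid_y)
           else numeric(0)
  in_t2 <- if (nrow(c1)) raster_extract(l2, c1$centroid_x, c1$centroid_y)
           else numeric(0)
  in_t1[is.na(in_t1)] <- 0; in_t2[is.na(in_t2)] <- 0
  pairs <- data.frame(id_t1 = as.integer(in_t1[in_t1 > 0]),
                      id_t2 = c2$id[in_t1 > 0])
  # crowns containing >= 2 centroids of the other survey
  multi_t1 <- as.integer(names(which(table(in_t1[in_t1 > 0]) >= 2)))
  multi_t2 <- as.integer(names(which(table(in_t2[in_t2 > 0]) >= 2)))
  bad <- pairs$id_t1 %in% multi_t1 | pairs$id_t2 %in% multi_t2
  ambiguous_t1 <- sort(unique(pairs$id_t1[bad]))
  pairs <- pairs[!bad, , drop = FALSE]
  stopifnot(!anyDuplicated(pairs$id_t1), !anyDuplicated(pairs$id_t2))
  rownames(pairs) <- NULL
  structure(list(
    pairs = pairs,
    ambiguous_t1 = ambiguous_t1,
    unmatched_t1 = setdiff(c1$id, c(pairs$id_t1, ambiguous_t1)),
    recruit_t2 = setdiff(c2$id, c2$id[in_t1 > 0]),
    crowns_t1 = crowns_t1, crowns_t2 = crowns_t2),
    class = "crown_matching")
}

#' @export
print.crown_matching <- function(x, ...) {
  cat("<crown_matching> ", nrow(x$pairs), " pairs, ",
      length(x$ambiguous_t1), " ambiguous, ", length(x$unmatched_t1),
      " unmatched t1, ", length(x$recruit_t2), " t2-only crowns\n", sep = "")
  invisible(x)
}

#' Classify the fate of every first-survey tree
#'
#' Matched pairs whose height or crown area declined by at least `threshold`
#' (relative to t1, boundary inclusive) are classed `dead_or_dieback`;
#' other matched pairs are `survived`. Unmatched t1 crowns are overlaid on
#' both CHMs: the maximum CHM height inside the t1 polygon at each date
#' gives their height change, the same threshold classes them
#' `dead_or_dieback`, and the remainder — trees that vanished from the
#' segmentation but not from the canopy — are `unresolved` (presumed
#' segmentation omissions, excluded from every rate). Trees flagged
#' ambiguous at matching stay `ambiguous_excluded`.
#'
#' @param matching a `crown_matching`.
#' @param chm_t1,chm_t2 the aligned survey CHMs.
#' @param threshold relative decline classed as death/dieback (default 0.30).
#' @return data.frame of class `matched_trees`, one row per t1 crown, with
#'   crown dimensions at both dates, relative declines (max- and mean-height
#'   based) and `status`.
#' @export
classify_fate <- function(matching, chm_t1, chm_t2, threshold = 0.30) {
  stopifnot(inherits(matching, "crown_matching"))
  cs1 <- matching$crowns_t1; cs2 <- matching$crowns_t2
  if (!identical(dim(chm_t1$values), dim(cs1$labels)) ||
      !identical(dim(chm_t2$values), dim(cs1$labels)))
    stop("CHMs and crown labels are on different grids")
  c1 <- cs1$crowns
  out <- data.frame(id_t1 = c1$id, id_t2 = NA_integer_,
                    x = c1$centroid_x, y = c1$centroid_y,
                    H_t1 = c1$H, H_mean_t1 = c1$H_mean, A_t1 = c1$A,
                    CD_t1 = c1$CD,
                    H_t2 = NA_real_, A_t2 = NA_real_, CD_t2 = NA_real_,
                    decline_h = NA_real_, decline_a = NA_real_,
                    decline_h_mean = NA_real_,
                    status = "unresolved", stringsAsFactors = FALSE)
  idx1 <- match(matching$pairs$id_t1, out$id_t1)
  idx2 <- match(matching$pairs$id_t2, cs2$crowns$id)
  out$id_t2[idx1] <- cs2$crowns$id[idx2]
  out$H_t2[idx1] <- cs2$crowns$H[idx2]
  out$A_t2[idx1] <- cs2$crowns$A[idx2]
  out$CD_t2[idx1] <- cs2$crowns$CD[idx2]
  out$decline_h[idx1] <- (out$H_t1[idx1] - out$H_t2[idx1]) / out$H_t1[idx1]
  out$decline_a[idx1] <- (out$A_t1[idx1] - out$A_t2[idx1]) / out$A_t1[idx1]
  out$decline_h_mean[idx1] <- (out$H_mean_t1[idx1] - cs2$crowns$H_mean[idx2]) /
    out$H_mean_t1[idx1]
  matched <- !is.na(out$id_t2)
  out$status[matched] <- ifelse(
    out$decline_h[matched] >= threshold | out$decline_a[matched] >= threshold,
    "dead_or_dieback", "survived")
  out$status[out$id_t1 %in% matching$ambiguous_t1] <- "ambiguous_excluded"

  un <- which(out$status == "unresolved")
  if (length(un)) {
    nr <- nrow(cs1$labels)
    idx <- which(cs1$labels > 0)
    lab <- cs1$labels[idx]
    keep <- lab %in% out$id_t1[un]
    idx <- idx[keep]; lab <- lab[keep]
    h1 <- tapply(chm_t1$values[idx], lab, max, na.rm = TRUE)
    h2v <- chm_t2$values[idx]
    if (all(is.na(h2v))) stop("t1 crown polygons fall entirely outside chm_t2")
    h2 <- tapply(h2v, lab, function(v)
      if (all(is.na(v))) stop("crown polygon outside chm_t2") else
        max(v, na.rm = TRUE))
    m <- match(out$id_t1[un], as.integer(names(h1)))
    dec <- (as.numeric(h1)[m] - as.numeric(h2)[m]) / as.numeric(h1)[m]
    out$decline_h[un] <- dec
    out$H_t2[un] <- as.numeric(h2)[m]
    out$status[un] <- ifelse(dec >= threshold, "dead_or_dieback",
                             "unresolved")
  }
  class(out) <- c("matched_trees", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Per-decade growth increments of surviving trees
#'
#' Linear per-decade scaling of the raw between-survey changes:
#' `delta * 10 / interval_years`. Negative increments short of the dieback
#' threshold are legitimate shrinkage and are retained.
#'
#' @param trees rows of a `matched_trees` table, survivors only.
#' @param interval_years years between surveys.
#' @return the table with `delta_h_decade` and `delta_a_decade` columns.
#' @export
growth_increments <- function(trees, interval_years) {
  if (any(trees$status != "survived"))
    stop("growth increments are defined for survivors only")
  k <- 10 / interval_years
  trees$delta_h_decade <- (trees$H_t2 - trees$H_t1) * k
  trees$delta_a_decade <- (trees$A_t2 - trees$A_t1) * k
  trees
}

#' Population mortality rate in three per-decade conventions
#'
#' The raw death fraction over the census interval, its linear per-decade
#' rescaling (`x 10/T`) and the compound annualised form
#' `1 - (1 - m)^(10/T)`. All three are reported because "% per decade" is
#' convention-dependent for intervals other than 10 years.
#'
#' @param n_dead,n_total dead and total (dead + survived) tree counts.
#' @param interval_years census interval (yr).
#' @return named list of percentages.
#' @export
mortality_rate <- function(n_dead, n_total, interval_years) {
  m <- n_dead / n_total
  list(raw_pct = 100 * m,
       linear_pct_decade = 100 * m * 10 / interval_years,
       compound_pct_decade = 100 * (1 - (1 - m)^(10 / interval_years)))
}
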