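#' Parameters for two-stage crown segmentation
#'
#' The segmentation is a seed-plus-region-growing delineation of the
#' *dalponte2016* family, run twice: a first pass with a broad local-maximum
#' search window sized for large crowns, then a second pass with a smaller
#' window over the pixels the first pass left unclaimed, to pick up small
#' trees missed in the shadow of large windows.
#'
#' The local-maximum search window is allometric: its diameter at pixel
#' height `h` is `window_scale * (seed_window_c * h^seed_window_d +
#' seed_window_floor_m)` metres, mirroring a crown-width/height allometry so
#' that tall pixels suppress competing maxima over a crown-sized
#' neighbourhood. The default coefficients match the synthetic generator's
#' crown allometry; when segmenting other data they should be re-fitted to a
#' local crown-width/height relationship.
#'
#' @param min_tree_height_m minimum tree height (m); crowns whose apex is not
#'   strictly taller are discarded.
#' @param min_crown_area_m2 minimum crown area (m^2); strict `>`.
#' @param seed_window_c,seed_window_d,seed_window_exp coefficients of the
#'   allometric window (power-law coefficient and exponent).
#' @param seed_window_floor_m additive window floor (m) so small trees retain
#'   a usable window.
#' @param broad_window_scale,small_window_scale window multipliers for pass 1
#'   and pass 2; pass 1 must use the larger window.
#' @param th_seed region-growing threshold: a pixel joins only if taller than
#'   `th_seed` times its seed's height. In (0, 1).
#' @param th_cr second threshold: the pixel must also exceed `th_cr` times
#'   the current region mean height. In (0, 1).
#' @param max_crown_diameter_scale cap on crown extent: pixels farther than
#'   `max_crown_diameter_scale * window(h) / 2` from the seed never join.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_tree_height_m = 4,
                                min_crown_area_m2 = 9,
                                seed_window_c = 1.2,
                                seed_window_d = 0.95,
                                seed_window_floor_m = 1.5,
                                broad_window_scale = 1,
                                small_window_scale = 0.5,
                                th_seed = 0.45,
                                th_cr = 0.55,
                                max_crown_diameter_scale = 3) {
  if (!(th_seed > 0 && th_seed < 1 && th_cr > 0 && th_cr < 1))
    stop("th_seed and th_cr must lie strictly between 0 and 1")
  if (broad_window_scale <= small_window_scale)
    stop("broad_window_scale must exceed small_window_scale")
  if (seed_window_c <= 0 || seed_window_floor_m < 0)
    stop("window coefficients must be positive")
  structure(list(min_tree_height_m = min_tree_height_m,
                 min_crown_area_m2 = min_crown_area_m2,
                 seed_window_c = seed_window_c,
                 seed_window_d = seed_window_d,
                 seed_window_floor_m = seed_window_floor_m,
                 broad_window_scale = broad_window_scale,
                 small_window_scale = small_window_scale,
                 th_seed = th_seed, th_cr = th_cr,
                 max_crown_diameter_scale = max_crown_diameter_scale),
            class = "segmentation_params")
}

seed_window_m <- function(params, h, scale = 1) {
  scale * (params$seed_window_c * h^params$seed_window_d +
             params$seed_window_floor_m)
}

#' Detect candidate tree apices as height-dependent local maxima
#'
#' A pixel is a seed when it is the strict maximum of a circular window whose
#' diameter grows allometrically with the pixel's own height, and is at least
#' `min_tree_height_m` tall. Equal-height ties are resolved in favour of the
#' first pixel in column-major scan order and flagged in the output.
#'
#' @param chm a CHM [height_raster].
#' @param params a [segmentation_params].
#' @param window_scale multiplier applied to the allometric window.
#' @return data.frame with `row`, `col`, `x`, `y`, `height`, `tie`.
#' @export
detect_seeds <- function(chm, params, window_scale = 1) {
  s <- cpp_detect_seeds(chm$values, params$min_tree_height_m,
                        params$seed_window_c, params$seed_window_d,
                        params$seed_window_floor_m, window_scale, chm$res)
  xy <- rowcol_to_xy(chm, s$row, s$col)
  data.frame(row = s$row, col = s$col, x = xy[, 1], y = xy[, 2],
             height = s$height, tie = as.logical(s$tie))
}

#' Grow crown regions from seeds
#'
#' Deterministic height-descending region growing: candidate pixels (4-
#' neighbours of already claimed pixels) are processed from a single global
#' queue ordered by height (descending), then pixel column-major index
#' (ascending), then seed id (ascending). A candidate joins its region iff it
#' is unclaimed, taller than `th_seed` times the seed height, taller than
#' `th_cr` times the current region mean, and within the allometric maximum
#' crown radius of the seed. Regions are pixel-disjoint by construction.
#'
#' @inheritParams detect_seeds
#' @param seeds data.frame from [detect_seeds()].
#' @return integer label matrix (0 = unclaimed), seed `i` labelled `i`.
#' @export
grow_regions <- function(chm, seeds, params, window_scale = 1) {
  if (nrow(seeds) == 0)
    return(matrix(0L, nrow(chm$values), ncol(chm$values)))
  max_rad <- params$max_crown_diameter_scale *
    seed_window_m(params, seeds$height, window_scale) / 2
  cpp_grow_regions(chm$values, seeds$row, seeds$col, max_rad,
                   params$th_seed, params$th_cr, chm$res)
}

#' Summarise labelled crowns into a crown table
#'
#' Height is the maximum CHM value inside the crown (the apex); crown area is
#' pixel count times pixel area (polygonization is exact pixel-boundary
#' tracing, so polygon area equals pixel area); crown diameter assumes a
#' circular crown, `CD = 2 * sqrt(A / pi)`. Mean crown height is kept
#' alongside the maximum.
#'
#' @param labels integer label matrix from [grow_regions()].
#' @param chm the CHM the labels were grown on.
#' @param survey survey label stored with each crown (e.g. `"t1"`).
#' @return data.frame with one row per crown.
#' @keywords internal
crown_table <- function(labels, chm, survey = "t1") {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(id = integer(), survey = character(),
                      apex_x = numeric(), apex_y = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      H = numeric(), H_mean = numeric(), A = numeric(),
                      CD = numeric(), n_pixels = integer()))
  nr <- nrow(labels)
  lab <- labels[idx]
  h <- chm$values[idx]
  row <- (idx - 1L) %% nr + 1L
  col <- (idx - 1L) %/% nr + 1L
  o <- order(lab, -h, idx)   # apex = tallest pixel, first in scan order
  first <- !duplicated(lab[o])
  apex_idx <- o[first]
  ids <- lab[apex_idx]
  npix <- as.integer(table(lab))
  stopifnot(identical(as.integer(names(table(lab))), ids[order(ids)]))
  xy <- rowcol_to_xy(chm, row, col)
  pa <- chm$res^2
  out <- data.frame(
    id = sort(unique(lab)),
    survey = survey,
    apex_x = xy[apex_idx, 1][order(ids)],
    apex_y = xy[apex_idx, 2][order(ids)],
    centroid_x = as.numeric(tapply(xy[, 1], lab, mean)),
    centroid_y = as.numeric(tapply(xy[, 2], lab, mean)),
    H = as.numeric(tapply(h, lab, max)),
    H_mean = as.numeric(tapply(h, lab, mean)),
    n_pixels = npix)
  out$A <- out$n_pixels * pa
  out$CD <- 2 * sqrt(out$A / pi)
  rownames(out) <- NULL
  out
}

#' Two-stage crown segmentation of a CHM
#'
#' Pass 1 detects seeds with the broad window and grows their regions; all
#' pixels claimed in pass 1 are then masked out (set to nodata) and pass 2
#' reruns detection and growth with the small window on the remainder, so
#' small crowns suppressed by the broad window are recovered without
#' disturbing pass-1 crowns. Crowns not strictly taller than
#' `min_tree_height_m` or not strictly larger than `min_crown_area_m2` are
#' removed, and survivors are relabelled `1..n` in pass order.
#'
#' @inheritParams detect_seeds
#' @param survey survey label for the crown table.
#' @return list of class `crown_set`: `crowns` (data.frame, see
#'   [crown_table]), `labels` (integer matrix), `chm` metadata and `params`.
#' @export
two_stage_segment <- function(chm, params = segmentation_params(),
                              survey = "t1") {
  seeds1 <- detect_seeds(chm, params, params$broad_window_scale)
  lab1 <- grow_regions(chm, seeds1, params, params$broad_window_scale)
  chm2 <- chm
  chm2$values[lab1 > 0] <- NA_real_
  seeds2 <- detect_seeds(chm2, params, params$small_window_scale)
  lab2 <- grow_regions(chm2, seeds2, params, params$small_window_scale)
  n1 <- max(0L, lab1)
  lab <- lab1
  lab[lab2 > 0] <- lab2[lab2 > 0] + n1
  crowns <- crown_table(lab, chm, survey)
  crowns$pass <- ifelse(crowns$id <= n1, 1L, 2L)
  keep <- crowns$H > params$min_tree_height_m &
    crowns$A > params$min_crown_area_m2
  crowns <- crowns[keep, , drop = FALSE]
  relab <- integer(max(lab, 1L))
  if (nrow(crowns)) relab[crowns$id] <- seq_len(nrow(crowns))
  lab_new <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  lab_new[nz] <- relab[lab[nz]]
  crowns$id <- seq_len(nrow(crowns))
  rownames(crowns) <- NULL
  structure(list(crowns = crowns, labels = lab_new,
                 raster = chm[c("xmin", "ymax", "res", "crs", "nodata")],
                 params = params, survey = survey),
            class = "crown_set")
}

#' @export
print.crown_set <- function(x, ...) {
  cat("<crown_set> ", nrow(x$crowns), " crowns (survey ", x$survey, ")\n",
      sep = "")
  invisible(x)
}

#' Benchmark a segmentation against reference crowns
#'
#' Predicted and reference crowns (label grids on the same raster) are
#' matched one-to-one greedily by decreasing intersection-over-union. A
#' reference crown is *correctly segmented* if its match exceeds the IoU
#' cut-off (default 50%); *oversegmented* if two or more predicted crowns
#' each cover more than `minor_overlap` of its area; *omitted* if no
#' predicted crown touches it. Precision is correct / predicted, recall is
#' correct / reference, and F1 their harmonic mean.
#'
#' @param predicted,reference `crown_set` objects (or bare label matrices)
#'   on the same grid.
#' @param iou_cutoff IoU fraction above which a match counts as correct.
#' @param minor_overlap overlap fraction (of the reference crown's area)
#'   above which a predicted crown counts towards oversegmentation.
#' @return list of class `segmentation_benchmark`.
#' @export
benchmark_segmentation <- function(predicted, reference, iou_cutoff = 0.5,
                                   minor_overlap = 0.1) {
  plab <- if (inherits(predicted, "crown_set")) predicted$labels else predicted
  rlab <- if (inherits(reference, "crown_set")) reference$labels else reference
  if (!identical(dim(plab), dim(rlab)))
    stop("predicted and reference label grids differ in size")
  rid <- sort(unique(rlab[rlab > 0]))
  pid <- sort(unique(plab[plab > 0]))
  if (length(rid) == 0) stop("reference crown set is empty; benchmark undefined")
  p_area <- table(factor(plab[plab > 0], levels = pid))
  r_area <- table(factor(rlab[rlab > 0], levels = rid))
  both <- plab > 0 & rlab > 0
  ov <- if (any(both)) {
    tab <- table(p = plab[both], r = rlab[both])
    d <- as.data.frame(tab, stringsAsFactors = FALSE)
    d <- d[d$Freq > 0, ]
    d$p <- as.integer(d$p); d$r <- as.integer(d$r)
    d
  } else data.frame(p = integer(), r = integer(), Freq = integer())
  ov$iou <- ov$Freq / (as.numeric(p_area[as.character(ov$p)]) +
                       as.numeric(r_area[as.character(ov$r)]) - ov$Freq)
  ov <- ov[order(-ov$iou, ov$r, ov$p), ]
  matched_p <- matched_r <- integer(0)
  pairs <- list()
  for (i in seq_len(nrow(ov))) {
    if (ov$p[i] %in% matched_p || ov$r[i] %in% matched_r) next
    matched_p <- c(matched_p, ov$p[i]); matched_r <- c(matched_r, ov$r[i])
    pairs[[length(pairs) + 1L]] <- ov[i, ]
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else ov[0, ]
  correct <- pairs$r[pairs$iou > iou_cutoff]
  n_overlapping <- tapply(
    ov$Freq / as.numeric(r_area[as.character(ov$r)]) > minor_overlap,
    ov$r, sum)
  overseg <- as.integer(names(n_overlapping))[n_overlapping >= 2]
  overseg <- setdiff(overseg, correct)
  omitted <- setdiff(rid, unique(ov$r))
  precision <- length(correct) / length(pid)
  recall <- length(correct) / length(rid)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  res <- chm_res_of(predicted)
  structure(list(
    n_detected = length(pid),
    n_reference = length(rid),
    mean_matched_area_m2 = if (nrow(pairs))
      mean(as.numeric(p_area[as.character(pairs$p)])) * res^2 else NA_real_,
    pct_correct = 100 * length(correct) / length(rid),
    pct_oversegmented = 100 * length(overseg) / length(rid),
    pct_omitted = 100 * length(omitted) / length(rid),
    mean_iou_pct = if (nrow(pairs)) 100 * mean(pairs$iou) else NA_real_,
    precision = precision, recall = recall, f1 = f1),
    class = "segmentation_benchmark")
}

chm_res_of <- function(x) {
  if (inherits(x, "crown_set")) x$raster$res else 1
}

#' @export
print.segmentation_benchmark <- function(x, ...) {
  cat("<segmentation_benchmark>\n")
  cat(sprintf("  detected %d / %d reference crowns\n", x$n_detected,
              x$n_reference))
  cat(sprintf("  correct %.1f%%  overseg %.1f%%  omitted %.1f%%\n",
              x$pct_correct, x$pct_oversegmented, x$pct_omitted))
  cat(sprintf("  mean IoU %.1f%%  P %.3f  R %.3f  F1 %.3f\n",
              x$mean_iou_pct, x$precision, x$recall, x$f1))
  invisible(x)
}
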