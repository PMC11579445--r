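#' Allometric coefficients for stem diameter and aboveground biomass
#'
#' Defaults are published allometries for Australian woodland and savanna
#' angiosperms: stem diameter from crown dimensions,
#' `DBH = 0.519 * (H * CD)^0.890 * CF_DBH` (cm, with `H`, `CD` in m and the
#' Baskerville back-transformation correction `CF_DBH = 1.002`), and
#' eucalypt aboveground biomass from stem diameter,
#' `AGB = 0.133 * DBH^2.375 * CF_AGB` (kg, `CF_AGB = 1.067`).
#'
#' @param dbh_coef,dbh_exp,cf_dbh DBH model coefficient, exponent and
#'   correction factor.
#' @param agb_coef,agb_exp,cf_agb AGB model coefficient, exponent and
#'   correction factor.
#' @return list of class `allometry_params`.
#' @export
allometry_params <- function(dbh_coef = 0.519, dbh_exp = 0.890,
                             cf_dbh = 1.002, agb_coef = 0.133,
                             agb_exp = 2.375, cf_agb = 1.067) {
  p <- list(dbh_coef = dbh_coef, dbh_exp = dbh_exp, cf_dbh = cf_dbh,
            agb_coef = agb_coef, agb_exp = agb_exp, cf_agb = cf_agb)
  if (any(unlist(p) <= 0)) stop("allometry parameters must be positive")
  structure(p, class = "allometry_params")
}

#' Stem diameter from height and crown diameter
#'
#' @param H tree height (m), positive.
#' @param CD crown diameter (m), positive.
#' @param params an [allometry_params].
#' @return DBH in cm.
#' @export
estimate_dbh <- function(H, CD, params = allometry_params()) {
  if (any(!is.finite(H) | H <= 0) || any(!is.finite(CD) | CD <= 0))
    stop("H and CD must be positive")
  params$dbh_coef * (H * CD)^params$dbh_exp * params$cf_dbh
}

#' Aboveground biomass from stem diameter
#'
#' @param DBH stem diameter (cm), positive.
#' @param params an [allometry_params].
#' @return AGB in kg.
#' @export
estimate_agb <- function(DBH, params = allometry_params()) {
  if (any(!is.finite(DBH) | DBH <= 0)) stop("DBH must be positive")
  params$agb_coef * DBH^params$agb_exp * params$cf_agb
}

#' Tree size metric
#'
#' The product of height and crown diameter (m^2), a strong correlate of
#' total aboveground biomass, computed from first-survey dimensions.
#'
#' @inheritParams estimate_dbh
#' @return H * CD (m^2).
#' @export
size_metric <- function(H, CD) H * CD

#' Per-tree aboveground biomass change
#'
#' Appends AGB at both dates and the per-decade biomass change to a
#' `matched_trees` table. Survivors change by the difference of their two
#' AGB estimates; trees classed dead or severe-dieback are assumed to have
#' lost all their biomass (AGB at t2 = 0), so their change is the full
#' `-AGB_t1`. Ambiguous and unresolved trees get `NA` — excluded, not
#' zeroed.
#'
#' @param trees a `matched_trees` table (see [classify_fate()]).
#' @param interval_years census interval (yr).
#' @param params an [allometry_params].
#' @return the table with `agb_t1`, `agb_t2`, `delta_agb_decade` (kg per
#'   decade) columns.
#' @export
agb_change <- function(trees, interval_years, params = allometry_params()) {
  trees$agb_t1 <- estimate_agb(estimate_dbh(trees$H_t1, trees$CD_t1, params),
                               params)
  trees$agb_t2 <- NA_real_
  surv <- trees$status == "survived"
  dead <- trees$status == "dead_or_dieback"
  if (any(surv))
    trees$agb_t2[surv] <- estimate_agb(
      estimate_dbh(trees$H_t2[surv], trees$CD_t2[surv], params), params)
  trees$agb_t2[dead] <- 0
  k <- 10 / interval_years
  trees$delta_agb_decade <- (trees$agb_t2 - trees$agb_t1) * k
  trees$delta_agb_decade[!(surv | dead)] <- NA_real_
  trees
}

#' Assign trees to size classes
#'
#' Two binning modes over the size metric `H x CD`: `"log_equal_width"`
#' cuts `log(size)` into `n_bins` equal-width intervals spanning the
#' observed range (the last bin closed on the right), chosen to spread a
#' right-skewed size distribution; `"percentile"` assigns equal tree counts
#' per bin (within one) by ranking, with ties resolved deterministically in
#' favour of the lower bin by first occurrence.
#'
#' @param size numeric vector of `H x CD` values (m^2).
#' @param mode `"log_equal_width"` or `"percentile"`.
#' @param n_bins number of classes (default 10).
#' @return list of class `size_bins`: `bin` (integer vector), `edges`
#'   (size-scale bin edges for log mode; quantile cut points for percentile
#'   mode), `mode`, `n_bins`.
#' @export
bin_trees <- function(size, mode = c("log_equal_width", "percentile"),
                      n_bins = 10) {
  mode <- match.arg(mode)
  if (length(size) < n_bins)
    stop("need at least n_bins trees to form size classes")
  if (any(size <= 0)) stop("size metric must be positive")
  if (diff(range(size)) == 0)
    stop("degenerate size distribution: all values identical")
  if (mode == "log_equal_width") {
    lo <- log(min(size)); hi <- log(max(size))
    brk <- seq(lo, hi, length.out = n_bins + 1)
    bin <- findInterval(log(size), brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
    edges <- exp(brk)
  } else {
    rk <- rank(size, ties.method = "first")
    bin <- ceiling(rk * n_bins / length(size))
    edges <- stats::quantile(size, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE)
  }
  structure(list(bin = as.integer(bin), edges = edges, mode = mode,
                 n_bins = n_bins), class = "size_bins")
}

wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

#' Size-resolved demographic and biomass rates
#'
#' Per size class: mean height-growth and crown-expansion rates of survivors
#' with normal-theory 95% confidence intervals of the mean; the probability
#' of death/severe dieback from a saturated binomial GLM on the size-class
#' factor (identical to the class's raw death proportion) with logit-scale
#' confidence intervals (Wilson intervals where a class is all-dead or
#' all-alive); biomass stocks at t1 and gains, losses and net change per
#' hectare and decade. Gains sum the biomass change of survivors, losses the
#' (negative) change of dead trees, and net = gains + losses by
#' construction, per class and in total.
#'
#' @param trees a `matched_trees` table with growth increments and
#'   [agb_change()] columns.
#' @param bins a `size_bins` over the same trees (t1 sizes).
#' @param area_ha mapped area (ha) for the per-hectare denominators.
#' @return data.frame, one row per size class, of class
#'   `size_class_summary`; totals in attribute `"totals"`.
#' @export
size_class_rates <- function(trees, bins, area_ha) {
  stopifnot(inherits(bins, "size_bins"), length(bins$bin) == nrow(trees))
  use <- trees$status %in% c("survived", "dead_or_dieback")
  n_bins <- bins$n_bins
  out <- data.frame(bin = seq_len(n_bins))
  ci_mean <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(c(NA, NA, NA))
    se <- stats::sd(v) / sqrt(length(v))
    c(mean(v), mean(v) + c(-1, 1) * stats::qt(0.975, length(v) - 1) * se)
  }
  mg_ha <- function(kg) kg / 1000 / area_ha
  for (b in seq_len(n_bins)) {
    sel <- bins$bin == b & use
    surv <- sel & trees$status == "survived"
    dead <- sel & trees$status == "dead_or_dieback"
    out$n_trees[b] <- sum(sel)
    out$empty[b] <- sum(sel) == 0
    gh <- ci_mean(trees$delta_h_decade[surv])
    ga <- ci_mean(trees$delta_a_decade[surv])
    out$mean_dh[b] <- gh[1]; out$dh_lo[b] <- gh[2]; out$dh_hi[b] <- gh[3]
    out$mean_da[b] <- ga[1]; out$da_lo[b] <- ga[2]; out$da_hi[b] <- ga[3]
    k <- sum(dead); n <- sum(sel)
    out$p_mortality[b] <- if (n > 0) k / n else NA_real_
    if (n > 0 && k > 0 && k < n) {
      # logit-scale Wald interval of the saturated binomial GLM
      lg <- log(k / (n - k))
      se <- sqrt(1 / k + 1 / (n - k))
      out$p_mort_lo[b] <- stats::plogis(lg - 1.96 * se)
      out$p_mort_hi[b] <- stats::plogis(lg + 1.96 * se)
    } else if (n > 0) {
      wi <- wilson_ci(k, n)
      out$p_mort_lo[b] <- wi[1]; out$p_mort_hi[b] <- wi[2]
    } else out$p_mort_lo[b] <- out$p_mort_hi[b] <- NA_real_
    out$agb_stock_mg_ha[b] <- mg_ha(sum(trees$agb_t1[sel]))
    out$gains_mg_ha_decade[b] <- mg_ha(sum(trees$delta_agb_decade[surv]))
    out$losses_mg_ha_decade[b] <- mg_ha(sum(trees$delta_agb_decade[dead]))
    out$net_mg_ha_decade[b] <- out$gains_mg_ha_decade[b] +
      out$losses_mg_ha_decade[b]
    out$mean_dbh_cm[b] <- if (any(sel))
      mean(estimate_dbh(trees$H_t1[sel], trees$CD_t1[sel])) else NA_real_
  }
  out$stock_fraction_pct <- 100 * out$agb_stock_mg_ha /
    sum(out$agb_stock_mg_ha)
  attr(out, "totals") <- list(
    agb_stock_mg_ha = sum(out$agb_stock_mg_ha),
    gains_mg_ha_decade = sum(out$gains_mg_ha_decade),
    losses_mg_ha_decade = sum(out$losses_mg_ha_decade),
    net_mg_ha_decade = sum(out$gains_mg_ha_decade) +
      sum(out$losses_mg_ha_decade))
  attr(out, "mode") <- bins$mode
  attr(out, "area_ha") <- area_ha
  class(out) <- c("size_class_summary", "data.frame")
  out
}

#' Whole-population demographic and biomass summary
#'
#' Computes the headline population quantities from a per-tree table:
#' mortality in the three per-decade conventions, mean growth rates of
#' survivors, biomass stocks per hectare at both dates, total gains, losses
#' and net change, and the share of t1 biomass held by the largest decile of
#' trees.
#'
#' @param trees a `matched_trees` table with growth and AGB columns.
#' @param area_ha mapped area (ha).
#' @param interval_years census interval (yr).
#' @return named list of scalars.
#' @export
demographic_summary <- function(trees, area_ha, interval_years) {
  surv <- trees$status == "survived"
  dead <- trees$status == "dead_or_dieback"
  n <- sum(surv | dead)
  mort <- mortality_rate(sum(dead), n, interval_years)
  size <- size_metric(trees$H_t1, trees$CD_t1)
  pb <- bin_trees(size[surv | dead], "percentile", 10)
  agb1 <- trees$agb_t1[surv | dead]
  list(n_tracked = n,
       n_dead = sum(dead),
       mortality_raw_pct = mort$raw_pct,
       mortality_linear_pct_decade = mort$linear_pct_decade,
       mortality_compound_pct_decade = mort$compound_pct_decade,
       mean_dh_m_decade = mean(trees$delta_h_decade[surv], na.rm = TRUE),
       mean_da_m2_decade = mean(trees$delta_a_decade[surv], na.rm = TRUE),
       agb_stock_t1_mg_ha = sum(trees$agb_t1[surv | dead]) / 1000 / area_ha,
       gains_mg_ha_decade = sum(trees$delta_agb_decade[surv]) / 1000 / area_ha,
       losses_mg_ha_decade = sum(trees$delta_agb_decade[dead]) / 1000 / area_ha,
       net_mg_ha_decade = sum(trees$delta_agb_decade[surv | dead]) / 1000 /
         area_ha,
       top_decile_stock_pct = 100 * sum(agb1[pb$bin == 10]) / sum(agb1))
}
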