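# Synthetic woodland scenes: paired CHMs, DTM, pulse-density fields and a
# ground-truth tree table with the statistical structure the analysis
# pipeline assumes (open-canopy stand, hard-core crown placement, allometric
# crown widths, wetness- and size-dependent growth and death).

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so generators are bit-reproducible without clobbering
#' the session's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Configuration of a synthetic woodland scene
#'
#' Defaults describe an open-canopy semi-arid eucalypt woodland: ~22 stems
#' per hectare, tree heights centred near 11 m within 4--22 m, crown
#' diameters following `CD = a * H^b` with lognormal scatter (mean crown area
#' near 125 m^2), crowns that do not overlap, a gently tilted terrain with a
#' sinuous drainage channel, a 9-year census interval and survey pulse
#' densities of 21.4 and 23.6 pulses per m^2. Growth slows in height and
#' accelerates in crown expansion with size; mortality risk declines with
#' size and wetness. All rates are expressed per decade and converted to the
#' census interval internally.
#'
#' @param extent_m scene width and height (m); must be divisible by both
#'   raster resolutions.
#' @param chm_res_m,dtm_res_m raster resolutions (m).
#' @param stem_density_per_ha target stem density.
#' @param height_range_m hard truncation bounds for tree height (m). The
#'   lower bound may sit below the 4-m analysis threshold; such trees exist
#'   in the scene and must be excluded downstream, not here.
#' @param height_meanlog,height_sdlog lognormal height distribution.
#' @param allom_a,allom_b,allom_sd crown allometry `CD = a*H^b*exp(e)`,
#'   `e ~ N(0, allom_sd)`.
#' @param min_crown_gap_m hard-core gap between crown edges (m).
#' @param crown_base_frac crown base height as a fraction of tree height;
#'   crowns are rendered as paraboloid caps from this base.
#' @param interval_years years between the two surveys.
#' @param growth_model,mortality_model named lists of demographic-rate
#'   parameters; see [scene_expected_growth()] and [scene_mortality_prob()].
#' @param dieback_fraction fraction of dying trees that undergo severe crown
#'   dieback (rendered shrunken in t2) instead of disappearing outright.
#' @param dieback_shrink multiplier applied to both height and crown radius
#'   of dieback trees.
#' @param pulse_density_mean named vector, mean pulses per m^2 per survey.
#' @param pulse_noise_sd,pulse_corr_m sd and correlation length (m) of the
#'   smooth pulse-density field.
#' @param chm_noise_sd_m additive Gaussian CHM noise (m), clipped at 0.
#' @param dtm_tilt,channel_depth_m,channel_sigma_m,dtm_rough_sd_m terrain
#'   shape: plane gradients (x, y), drainage channel depth and width, and sd
#'   of the smooth roughness field.
#' @param twi_ref,neigh_ref_m,pd_ref centring constants for the covariate
#'   effects in the growth and mortality models.
#' @param rng_seed integer; the same seed reproduces the scene bit for bit.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(extent_m = c(500, 500),
                         chm_res_m = 0.5, dtm_res_m = 5,
                         stem_density_per_ha = 22,
                         height_range_m = c(4, 22),
                         height_meanlog = log(10.5), height_sdlog = 0.25,
                         allom_a = 1.2, allom_b = 0.95, allom_sd = 0.12,
                         min_crown_gap_m = 2,
                         crown_base_frac = 0.4,
                         interval_years = 9,
                         growth_model = list(
                           hg_floor = 0.06, hg_amp = 0.5, hg_scale = 60,
                           twi_effect_h = 0.05, comp_effect_h = 0.03,
                           pd_effect_h = 0.02, sd_h = 0.2,
                           ca_floor = 7, ca_amp = 9.5, ca_scale = 180,
                           twi_effect_a = 0.8, comp_effect_a = 0.5,
                           pd_effect_a = 0.4, sd_a = 8),
                         mortality_model = list(
                           intercept = -1.96, size_slope = -0.39,
                           twi_slope = -0.25, comp_slope = 0.15),
                         dieback_fraction = 0.25, dieback_shrink = 0.5,
                         pulse_density_mean = c(t1 = 21.4, t2 = 23.6),
                         pulse_noise_sd = 1.5, pulse_corr_m = 100,
                         chm_noise_sd_m = 0,
                         dtm_tilt = c(0.002, 0.001),
                         channel_depth_m = 3, channel_sigma_m = 15,
                         dtm_rough_sd_m = 0.2,
                         twi_ref = 5, neigh_ref_m = 1.5, pd_ref = 2.2,
                         rng_seed = 1L) {
  stopifnot(length(extent_m) == 2, all(extent_m > 0),
            chm_res_m > 0, dtm_res_m > 0, stem_density_per_ha > 0,
            length(height_range_m) == 2,
            height_range_m[1] > 0, diff(height_range_m) > 0,
            allom_a > 0, allom_b > 0, allom_sd >= 0,
            min_crown_gap_m >= 0, interval_years > 0,
            crown_base_frac >= 0, crown_base_frac < 1,
            dieback_fraction >= 0, dieback_fraction <= 1,
            dieback_shrink > 0, dieback_shrink < 1,
            all(pulse_density_mean > 0), pulse_noise_sd >= 0,
            chm_noise_sd_m >= 0, height_sdlog > 0)
  structure(as.list(environment()), class = "scene_config")
}

# bilinearly interpolated white noise: a smooth random field with marginal
# sd ~ `sd` and correlation length ~ `corr_m`
smooth_field <- function(nr, nc, res, corr_m, sd) {
  if (sd == 0) return(matrix(0, nr, nc))
  cnr <- max(2L, ceiling(nr * res / corr_m) + 1L)
  cnc <- max(2L, ceiling(nc * res / corr_m) + 1L)
  z <- matrix(stats::rnorm(cnr * cnc), cnr, cnc)
  rows <- seq(1, cnr, length.out = nr)
  cols <- seq(1, cnc, length.out = nc)
  z2 <- apply(z, 2, function(v) stats::approx(seq_len(cnr), v, rows)$y)
  z3 <- t(apply(z2, 1, function(v) stats::approx(seq_len(cnc), v, cols)$y))
  z3 * sd
}

#' Generate the synthetic terrain model
#'
#' A gently tilted plane carved by a sinuous drainage channel (a negative
#' Gaussian ridge along a sine polyline) plus a smooth roughness field, so
#' that topographic wetness varies across the scene the way it does over the
#' drainage network of a flat semi-arid site.
#'
#' @param config a [scene_config].
#' @return a [height_raster] at `dtm_res_m`; the channel polyline is attached
#'   as attribute `"channel"`.
#' @export
generate_dtm <- function(config) {
  res <- config$dtm_res_m
  nc <- config$extent_m[1] / res
  nr <- config$extent_m[2] / res
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("extent must be divisible by the DTM resolution")
  nc <- as.integer(round(nc)); nr <- as.integer(round(nr))
  if (nr < 3 || nc < 3) stop("degenerate extent: DTM smaller than 3x3 cells")
  xs <- (seq_len(nc) - 0.5) * res
  ys <- config$extent_m[2] - (seq_len(nr) - 0.5) * res
  z <- 450 + outer(ys, xs, function(y, x)
    config$dtm_tilt[1] * x + config$dtm_tilt[2] * y)
  cx <- seq(0, config$extent_m[1], by = res / 2)
  cy <- config$extent_m[2] * (0.5 + 0.2 * sin(2 * pi * cx / config$extent_m[1]))
  if (config$channel_depth_m > 0) {
    d2 <- matrix(Inf, nr, nc)
    for (k in seq_along(cx)) {
      dd <- outer(ys, xs, function(y, x) (x - cx[k])^2 + (y - cy[k])^2)
      d2 <- pmin(d2, dd)
    }
    z <- z - config$channel_depth_m * exp(-d2 / (2 * config$channel_sigma_m^2))
  }
  z <- z + with_seed(config$rng_seed + 11L,
                     smooth_field(nr, nc, res, 60, config$dtm_rough_sd_m))
  r <- height_raster(z, xmin = 0, ymax = config$extent_m[2], res = res)
  attr(r, "channel") <- cbind(x = cx, y = cy)
  r
}

#' Expected per-decade growth of the synthetic demographic model
#'
#' Height growth declines exponentially with tree size while crown-area
#' growth saturates upward, plus linear effects of centred topographic
#' wetness, neighbourhood canopy height and pulse-density difference.
#'
#' @param config a [scene_config].
#' @param size tree size `H * CD` (m^2).
#' @param twi topographic wetness index at the stem.
#' @param neigh neighbourhood canopy height (m).
#' @param pd_diff pulse-density difference (pulses per m^2).
#' @return list with components `h` (m per decade) and `a` (m^2 per decade).
#' @export
scene_expected_growth <- function(config, size, twi = config$twi_ref,
                                  neigh = config$neigh_ref_m,
                                  pd_diff = config$pd_ref) {
  g <- config$growth_model
  list(
    h = g$hg_floor + g$hg_amp * exp(-size / g$hg_scale) +
      g$twi_effect_h * (twi - config$twi_ref) +
      g$comp_effect_h * (neigh - config$neigh_ref_m) +
      g$pd_effect_h * (pd_diff - config$pd_ref),
    a = g$ca_floor + g$ca_amp * (1 - exp(-size / g$ca_scale)) +
      g$twi_effect_a * (twi - config$twi_ref) +
      g$comp_effect_a * (neigh - config$neigh_ref_m) +
      g$pd_effect_a * (pd_diff - config$pd_ref))
}

#' Probability of death over the census interval
#'
#' Logistic in log tree size (centred at 100 m^2), centred wetness and
#' centred neighbourhood height.
#'
#' @inheritParams scene_expected_growth
#' @return numeric vector of probabilities.
#' @export
scene_mortality_prob <- function(config, size, twi = config$twi_ref,
                                 neigh = config$neigh_ref_m) {
  m <- config$mortality_model
  stats::plogis(m$intercept + m$size_slope * (log(size) - log(100)) +
                  m$twi_slope * (twi - config$twi_ref) +
                  m$comp_slope * (neigh - config$neigh_ref_m))
}

#' Place trees and assign their demography
#'
#' Draws tree sizes, places stems by largest-first dart throwing under a
#' hard-core constraint (crown discs separated by at least the configured
#' gap), samples each stem's topographic wetness from the TWI surface of the
#' supplied DTM, computes a true neighbourhood canopy-height proxy from the
#' surrounding crowns, and assigns growth and death from the configured
#' demographic models.
#'
#' @param config a [scene_config].
#' @param dtm terrain raster from [generate_dtm()] (regenerated if omitted).
#' @return data.frame of class `scene_truth`; the config is attached as
#'   attribute `"config"`.
#' @export
place_trees <- function(config, dtm = generate_dtm(config)) {
  ext <- config$extent_m
  area_ha <- prod(ext) / 1e4
  n_target <- round(config$stem_density_per_ha * area_ha)
  twi_raster <- compute_twi(fill_sinks(dtm))
  out <- with_seed(config$rng_seed + 23L, {
    h <- numeric(0)
    while (length(h) < n_target) {
      cand <- stats::rlnorm(n_target * 2, config$height_meanlog,
                            config$height_sdlog)
      cand <- cand[cand >= config$height_range_m[1] &
                     cand <= config$height_range_m[2]]
      h <- c(h, cand)
    }
    h <- h[seq_len(n_target)]
    cd <- config$allom_a * h^config$allom_b *
      exp(stats::rnorm(n_target, 0, config$allom_sd))
    r_cr <- cd / 2
    o <- order(-r_cr)   # largest first packs dense stands reliably
    h <- h[o]; r_cr <- r_cr[o]
    x <- y <- numeric(n_target)
    placed <- 0L
    max_attempts <- 400L
    for (i in seq_len(n_target)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        px <- stats::runif(1, r_cr[i], ext[1] - r_cr[i])
        py <- stats::runif(1, r_cr[i], ext[2] - r_cr[i])
        if (placed == 0L) { ok <- TRUE }
        else {
          j <- seq_len(placed)
          mind <- sqrt((x[j] - px)^2 + (y[j] - py)^2) -
            (r_cr[j] + r_cr[i] + config$min_crown_gap_m)
          ok <- all(mind >= 0)
        }
        if (ok) { placed <- placed + 1L
          x[placed] <- px; y[placed] <- py
          h[placed] <- h[i]; r_cr[placed] <- r_cr[i]
          break }
      }
    }
    n <- placed
    if (n < 0.8 * n_target)
      stop(sprintf(paste0("hard-core placement infeasible: achieved %.1f ",
                          "trees/ha of %.1f targeted"),
                   n / area_ha, config$stem_density_per_ha))
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
    h <- h[seq_len(n)]; r_cr <- r_cr[seq_len(n)]

    twi <- raster_extract(twi_raster, x, y)
    # true neighbourhood canopy height: mean rendered height of neighbouring
    # crowns over the 25-m disc (paraboloid mean height = H*(1+base)/2)
    neigh <- vapply(seq_len(n), function(i) {
      d <- sqrt((x - x[i])^2 + (y - y[i])^2)
      j <- which(d > 0 & d < 25 + r_cr)
      sum(pi * r_cr[j]^2 * h[j] * (1 + config$crown_base_frac) / 2) /
        (pi * 25^2)
    }, numeric(1))

    size <- h * (2 * r_cr)
    k <- config$interval_years / 10
    eg <- scene_expected_growth(config, size, twi, neigh)
    g <- config$growth_model
    dh_dec <- eg$h + stats::rnorm(n, 0, g$sd_h)
    da_dec <- eg$a + stats::rnorm(n, 0, g$sd_a)
    p_die <- scene_mortality_prob(config, size, twi, neigh)
    died <- stats::runif(n) < p_die
    dieback <- died & stats::runif(n) < config$dieback_fraction

    h2 <- pmax(0, h + dh_dec * k)
    a2 <- pmax(1, pi * r_cr^2 + da_dec * k)
    r2 <- sqrt(a2 / pi)
    h2[died] <- ifelse(dieback[died], h[died] * config$dieback_shrink, NA)
    r2[died] <- ifelse(dieback[died], r_cr[died] * config$dieback_shrink, NA)

    data.frame(id = seq_len(n), x = x, y = y,
               H_t1 = h, crown_radius_t1 = r_cr,
               H_t2 = h2, crown_radius_t2 = r2,
               died = died, dieback = dieback,
               twi_true = twi, neigh_true = neigh,
               p_death = p_die,
               delta_h_decade = dh_dec, delta_a_decade = da_dec)
  })
  attr(out, "config") <- config
  class(out) <- c("scene_truth", "data.frame")
  out
}

#' Render a canopy height model from scene truth
#'
#' Each tree present in the requested survey is rendered as a paraboloid
#' crown cap, `h(r) = H - (H - H_base) * (r/R)^2` for `r <= R` with
#' `H_base = crown_base_frac * H`, onto a zero ground; overlapping crowns
#' take the pixelwise maximum. Trees that died without dieback are absent
#' from t2; dieback trees appear shrunken. Optional additive Gaussian noise
#' is clipped at zero.
#'
#' @param truth a `scene_truth` from [place_trees()].
#' @param survey `"t1"` or `"t2"`.
#' @param config the scene's [scene_config] (defaults to the one attached to
#'   `truth`).
#' @return a CHM [height_raster] at `chm_res_m`.
#' @export
render_chm <- function(truth, survey = c("t1", "t2"),
                       config = attr(truth, "config")) {
  survey <- match.arg(survey)
  res <- config$chm_res_m
  nc <- as.integer(round(config$extent_m[1] / res))
  nr <- as.integer(round(config$extent_m[2] / res))
  z <- matrix(0, nr, nc)
  if (survey == "t1") {
    keep <- rep(TRUE, nrow(truth))
    H <- truth$H_t1; R <- truth$crown_radius_t1
  } else {
    keep <- !truth$died | truth$dieback
    H <- truth$H_t2; R <- truth$crown_radius_t2
  }
  for (i in which(keep)) {
    if (!is.finite(H[i]) || !is.finite(R[i]) || R[i] <= 0) next
    c0 <- max(1L, floor((truth$x[i] - R[i]) / res) + 1L)
    c1 <- min(nc, ceiling((truth$x[i] + R[i]) / res))
    r0 <- max(1L, floor((config$extent_m[2] - truth$y[i] - R[i]) / res) + 1L)
    r1 <- min(nr, ceiling((config$extent_m[2] - truth$y[i] + R[i]) / res))
    if (c1 < c0 || r1 < r0) next
    px <- (seq(c0, c1) - 0.5) * res
    py <- config$extent_m[2] - (seq(r0, r1) - 0.5) * res
    d2 <- outer(py, px, function(yy, xx) (xx - truth$x[i])^2 + (yy - truth$y[i])^2)
    hb <- config$crown_base_frac * H[i]
    crown <- H[i] - (H[i] - hb) * d2 / R[i]^2
    crown[d2 > R[i]^2] <- 0
    block <- z[r0:r1, c0:c1]
    z[r0:r1, c0:c1] <- pmax(block, crown)
  }
  if (config$chm_noise_sd_m > 0) {
    off <- if (survey == "t1") 101L else 102L
    z <- with_seed(config$rng_seed + off,
                   pmax(z + stats::rnorm(length(z), 0,
                                         config$chm_noise_sd_m), 0))
  }
  height_raster(z, xmin = 0, ymax = config$extent_m[2], res = res)
}

#' Render a survey's pulse-density field
#'
#' A smooth positive field around the survey's configured mean pulse
#' density, emulating the flightline-scale variation of real acquisitions.
#'
#' @inheritParams render_chm
#' @return a [height_raster] at the DTM resolution.
#' @export
render_pulse_density <- function(config, survey = c("t1", "t2")) {
  survey <- match.arg(survey)
  mu <- config$pulse_density_mean[[survey]]
  if (!is.finite(mu) || mu <= 0) stop("pulse density mean must be positive")
  res <- config$dtm_res_m
  nc <- as.integer(round(config$extent_m[1] / res))
  nr <- as.integer(round(config$extent_m[2] / res))
  off <- if (survey == "t1") 301L else 302L
  f <- with_seed(config$rng_seed + off,
                 smooth_field(nr, nc, res, config$pulse_corr_m,
                              config$pulse_noise_sd))
  height_raster(pmax(mu + f, 0.1), xmin = 0, ymax = config$extent_m[2],
                res = res)
}

#' Simulate a tree table directly from the demographic model
#'
#' Distribution-level counterpart of the full scene renderer: draws sizes,
#' wetness, neighbourhood height and pulse-density difference from their
#' marginal distributions and responses from the configured growth and
#' mortality models, without rasters or segmentation. Used for statistical
#' parameter-recovery checks at sample sizes no rendered scene could hold.
#'
#' @param n number of trees.
#' @param config a [scene_config].
#' @param seed RNG seed.
#' @return data.frame with tree locations, covariates and responses.
#' @export
simulate_tree_table <- function(n, config = scene_config(), seed = 1L) {
  with_seed(seed, {
    h <- stats::rlnorm(n, config$height_meanlog, config$height_sdlog)
    h <- pmin(pmax(h, config$height_range_m[1]), config$height_range_m[2])
    cd <- config$allom_a * h^config$allom_b *
      exp(stats::rnorm(n, 0, config$allom_sd))
    size <- h * cd
    twi <- config$twi_ref + stats::rnorm(n, 0, 1.2)
    neigh <- pmax(0, config$neigh_ref_m + stats::rnorm(n, 0, 1))
    pd <- config$pd_ref + stats::rnorm(n, 0, 1.5)
    eg <- scene_expected_growth(config, size, twi, neigh, pd)
    g <- config$growth_model
    p <- scene_mortality_prob(config, size, twi, neigh)
    data.frame(
      id = seq_len(n),
      x = stats::runif(n, 0, 1000), y = stats::runif(n, 0, 1000),
      H_t1 = h, CD_t1 = cd, size = size,
      twi = twi, neigh = neigh, pd_diff = pd,
      delta_h_decade = eg$h + stats::rnorm(n, 0, g$sd_h),
      delta_a_decade = eg$a + stats::rnorm(n, 0, g$sd_a),
      p_death = p,
      died = stats::runif(n) < p)
  })
}

#' Write and read a scene configuration as YAML
#'
#' @param config a [scene_config].
#' @param path file path.
#' @return `read_scene_config` returns a [scene_config].
#' @export
write_scene_config <- function(config, path) {
  x <- unclass(config)
  x$pulse_density_mean <- as.list(x$pulse_density_mean)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$pulse_density_mean <- unlist(x$pulse_density_mean)
  for (nm in c("extent_m", "height_range_m", "dtm_tilt"))
    x[[nm]] <- as.numeric(unlist(x[[nm]]))
  do.call(scene_config, x)
}

#' Write all artefacts of a synthetic scene to a directory
#'
#' CHMs, DTM and pulse-density rasters as GeoTIFF, the truth table as CSV
#' and the configuration as YAML.
#'
#' @param truth a `scene_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, dir) {
  config <- attr(truth, "config")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geotiff(render_chm(truth, "t1", config), file.path(dir, "chm_t1.tif"))
  write_geotiff(render_chm(truth, "t2", config), file.path(dir, "chm_t2.tif"))
  write_geotiff(generate_dtm(config), file.path(dir, "dtm.tif"))
  write_geotiff(render_pulse_density(config, "t1"),
                file.path(dir, "pulse_t1.tif"))
  write_geotiff(render_pulse_density(config, "t2"),
                file.path(dir, "pulse_t2.tif"))
  utils::write.csv(as.data.frame(truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  write_scene_config(config, file.path(dir, "config.yml"))
  invisible(dir)
}
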