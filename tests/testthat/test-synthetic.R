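small_cfg <- function(...) {
  args <- utils::modifyList(
    list(extent_m = c(150, 150), stem_density_per_ha = 16,
         min_crown_gap_m = 3, rng_seed = 11),
    list(...))
  do.call(scene_config, args)
}

test_that("every generator output is deterministic under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(generate_dtm(cfg)$values, generate_dtm(cfg)$values)
  tr1 <- place_trees(cfg); tr2 <- place_trees(cfg)
  expect_identical(tr1, tr2)
  expect_identical(render_chm(tr1, "t1")$values, render_chm(tr2, "t1")$values)
  expect_identical(render_pulse_density(cfg, "t1")$values,
                   render_pulse_density(cfg, "t1")$values)
  cfg2 <- small_cfg(rng_seed = 12)
  expect_false(identical(place_trees(cfg2)$x, tr1$x))
})

test_that("terrain generator produces a channel and honours degenerate cases", {
  cfg <- small_cfg()
  dtm <- generate_dtm(cfg)
  ch <- attr(dtm, "channel")
  # the lowest cell lies within 2 cell widths of the channel polyline
  amin <- which(dtm$values == min(dtm$values), arr.ind = TRUE)[1, ]
  xy <- rowcol_to_xy(dtm, amin[1], amin[2])
  dmin <- min(sqrt((ch[, 1] - xy[1])^2 + (ch[, 2] - xy[2])^2))
  expect_lt(dmin, 2 * cfg$dtm_res_m)

  # no channel, no roughness, tilt along x only: a plane, constant down rows
  flat <- small_cfg(channel_depth_m = 0, dtm_rough_sd_m = 0,
                    dtm_tilt = c(0.01, 0))
  zp <- generate_dtm(flat)$values
  expect_equal(max(apply(zp, 2, function(v) diff(range(v)))), 0)

  expect_error(generate_dtm(small_cfg(extent_m = c(10, 10))), "degenerate")
})

test_that("tree placement hits the target density under the hard-core rule", {
  cfg <- scene_config(extent_m = c(500, 500), min_crown_gap_m = 5,
                      rng_seed = 5)
  tr <- place_trees(cfg)
  n_target <- 22 * 25
  expect_gte(nrow(tr), 0.95 * n_target)
  expect_lte(nrow(tr), n_target)
  # hard-core: no two crown discs closer than the gap
  d <- as.matrix(dist(cbind(tr$x, tr$y)))
  lim <- outer(tr$crown_radius_t1, tr$crown_radius_t1, "+") + 5
  diag(d) <- Inf
  expect_true(all(d >= lim - 1e-9))
})

test_that("the configured crown allometry is recoverable from the truth table", {
  cfg <- scene_config(extent_m = c(1000, 1000), rng_seed = 2)
  tr <- place_trees(cfg)
  fit <- lm(log(2 * crown_radius_t1) ~ log(H_t1), data = tr)
  est <- coef(summary(fit))
  expect_lt(abs(est["log(H_t1)", "Estimate"] - cfg$allom_b),
            2 * est["log(H_t1)", "Std. Error"])
})

test_that("mortality falls with wetness when the TWI slope is negative", {
  cfg <- scene_config()
  tt <- simulate_tree_table(10000, cfg, seed = 4)
  q <- quantile(tt$twi, c(0.25, 0.75))
  p_low <- mean(tt$died[tt$twi <= q[1]])
  p_high <- mean(tt$died[tt$twi >= q[2]])
  expect_lt(p_high, p_low)
})

test_that("growth is a deterministic function of size when effects and noise are off", {
  cfg <- scene_config(growth_model = list(
    hg_floor = 0.06, hg_amp = 0.5, hg_scale = 120,
    twi_effect_h = 0, comp_effect_h = 0, pd_effect_h = 0, sd_h = 0,
    ca_floor = 7, ca_amp = 9.5, ca_scale = 180,
    twi_effect_a = 0, comp_effect_a = 0, pd_effect_a = 0, sd_a = 0))
  tt <- simulate_tree_table(500, cfg, seed = 9)
  expected <- scene_expected_growth(cfg, tt$size)$h
  expect_equal(tt$delta_h_decade, expected)
})

test_that("a single rendered crown has the analytic apex height and footprint", {
  cfg <- small_cfg(chm_noise_sd_m = 0)
  # apex on a pixel centre so the rendered maximum is exactly H
  tr <- data.frame(id = 1L, x = 75.25, y = 75.25,
                   H_t1 = 10, crown_radius_t1 = 4,
                   H_t2 = 10, crown_radius_t2 = 4,
                   died = FALSE, dieback = FALSE)
  attr(tr, "config") <- cfg
  chm <- render_chm(tr, "t1", cfg)
  expect_equal(max(chm$values), 10)
  n_px <- sum(chm$values > 0)
  expect_lt(abs(n_px - pi * 16 / 0.25), 10)   # disc area vs pixel count
  # crown base: lowest nonzero pixel near 0.4 * H
  expect_gte(min(chm$values[chm$values > 0]), 0.4 * 10 - 0.5)
})

test_that("rendering respects survival, death and unchanged survivors", {
  cfg <- small_cfg(chm_noise_sd_m = 0)
  tr0 <- data.frame(id = integer(), x = numeric(), y = numeric(),
                    H_t1 = numeric(), crown_radius_t1 = numeric(),
                    H_t2 = numeric(), crown_radius_t2 = numeric(),
                    died = logical(), dieback = logical())
  expect_true(all(render_chm(tr0, "t1", cfg)$values == 0))

  tr <- data.frame(id = 1:2, x = c(40, 110), y = c(40, 110),
                   H_t1 = c(10, 12), crown_radius_t1 = c(4, 5),
                   H_t2 = c(10, NA), crown_radius_t2 = c(4, NA),
                   died = c(FALSE, TRUE), dieback = c(FALSE, FALSE))
  attr(tr, "config") <- cfg
  c1 <- render_chm(tr, "t1", cfg); c2 <- render_chm(tr, "t2", cfg)
  # the dead tree vanishes; the unchanged survivor keeps its footprint
  expect_gt(sum(c1$values > 0), sum(c2$values > 0))
  win <- c1$values[1:160, 1:160]; win2 <- c2$values[1:160, 1:160]
  expect_identical(win > 0, win2 > 0)
  expect_equal(win, win2)
  # apex pixel height equals tree height within half-pixel sampling error
  rc <- xy_to_rowcol(c1, tr$x, tr$y)
  expect_lt(max(abs(c1$values[rc] - tr$H_t1)), 0.35)
})

test_that("pulse-density fields have the configured means and difference", {
  cfg0 <- small_cfg(pulse_noise_sd = 0)
  p1 <- render_pulse_density(cfg0, "t1")
  expect_true(all(p1$values == 21.4))
  cfg <- small_cfg()
  d <- render_pulse_density(cfg, "t2")$values -
    render_pulse_density(cfg, "t1")$values
  expect_equal(mean(d), 23.6 - 21.4, tolerance = 0.25)
  cfg_bad <- small_cfg()
  cfg_bad$pulse_density_mean["t2"] <- -1
  expect_error(render_pulse_density(cfg_bad, "t2"), "positive")
})

test_that("scene truth honours its structural invariants", {
  cfg <- small_cfg(dieback_fraction = 0)
  tr <- place_trees(cfg)
  chm2 <- render_chm(tr, "t2")
  # outright deaths leave no trace in the t2 CHM at their apex
  rc <- xy_to_rowcol(chm2, tr$x[tr$died], tr$y[tr$died])
  if (nrow(rc)) expect_true(all(chm2$values[rc] < 4))
  expect_true(all(tr$H_t2[!tr$died] >= 0))
  expect_true(all(tr$crown_radius_t2[!tr$died] >= 0))
})

test_that("scene config and artefacts survive a disk round trip", {
  cfg <- small_cfg()
  f <- tempfile(fileext = ".yml")
  write_scene_config(cfg, f)
  cfg2 <- read_scene_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
  dir <- tempfile()
  tr <- place_trees(cfg)
  write_scene(tr, dir)
  expect_true(all(file.exists(file.path(dir,
    c("chm_t1.tif", "chm_t2.tif", "dtm.tif", "pulse_t1.tif",
      "pulse_t2.tif", "truth.csv", "config.yml")))))
  chm_back <- read_geotiff(file.path(dir, "chm_t1.tif"))
  expect_identical(chm_back$values, render_chm(tr, "t1")$values)
})
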