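# A hand-built crown_set with rectangular crowns at known positions, for
# exact-arithmetic matching and fate cases.
fake_crown_set <- function(rects, nr = 60, nc = 60, res = 0.5, heights = NULL,
                           survey = "t1") {
  lab <- matrix(0L, nr, nc)
  chm <- matrix(0, nr, nc)
  for (i in seq_along(rects)) {
    rc <- rects[[i]]
    lab[rc[1]:rc[2], rc[3]:rc[4]] <- i
    chm[rc[1]:rc[2], rc[3]:rc[4]] <- if (is.null(heights)) 10 else heights[i]
  }
  chm_r <- height_raster(chm, res = res)
  cs <- structure(list(
    crowns = crowndynamics:::crown_table(lab, chm_r, survey),
    labels = lab,
    raster = chm_r[c("xmin", "ymax", "res", "crs", "nodata")],
    params = segmentation_params(), survey = survey), class = "crown_set")
  list(cs = cs, chm = chm_r)
}

test_that("identical crown sets match one-to-one with zero change", {
  a <- fake_crown_set(list(c(5, 14, 5, 14), c(30, 39, 30, 39)),
                      heights = c(10, 15))
  m <- match_crowns(a$cs, a$cs)
  expect_equal(nrow(m$pairs), 2)
  expect_equal(length(m$ambiguous_t1), 0)
  expect_equal(length(m$unmatched_t1), 0)
  expect_equal(length(m$recruit_t2), 0)
  mt <- classify_fate(m, a$chm, a$chm)
  expect_true(all(mt$status == "survived"))
  gi <- growth_increments(mt, 9)
  expect_true(all(gi$delta_h_decade == 0))
  expect_true(all(gi$delta_a_decade == 0))
})

test_that("a crown containing two centroids is excluded as ambiguous", {
  big <- fake_crown_set(list(c(5, 24, 5, 24)))               # one t1 crown
  two <- fake_crown_set(list(c(6, 12, 6, 12), c(16, 22, 16, 22)),
                        survey = "t2")                       # both inside it
  m <- match_crowns(big$cs, two$cs)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$ambiguous_t1, 1L)
  mt <- classify_fate(m, big$chm, two$chm)
  expect_equal(mt$status, "ambiguous_excluded")
})

test_that("fate classification follows the 30% decline rule on either axis", {
  # three t1 crowns; t2 counterparts shrunk or lowered to controlled degrees
  t1 <- fake_crown_set(list(c(1, 10, 1, 10), c(1, 10, 21, 30),
                            c(1, 10, 41, 50)),
                       heights = c(10, 10, 10))
  # crown 1: height 10 -> 6.9 (-31%): dead. crown 2: height -25% but area
  # -36% (100 -> 64 px): dead by the and/or rule. crown 3: -10%: survives.
  t2 <- fake_crown_set(list(c(1, 10, 1, 10), c(2, 9, 22, 29),
                            c(1, 10, 41, 50)),
                       heights = c(6.9, 7.5, 9), survey = "t2")
  m <- match_crowns(t1$cs, t2$cs)
  mt <- classify_fate(m, t1$chm, t2$chm)
  expect_equal(mt$status, c("dead_or_dieback", "dead_or_dieback", "survived"))
  expect_equal(mt$decline_h, c(0.31, 0.25, 0.10), tolerance = 1e-12)
  expect_equal(mt$decline_a[2], 1 - 64 / 100)

  # boundary is inclusive: exactly 30% decline counts as dead
  t2b <- fake_crown_set(list(c(1, 10, 1, 10), c(2, 9, 22, 29),
                             c(1, 10, 41, 50)),
                        heights = c(7, 7.5, 9), survey = "t2")
  mtb <- classify_fate(match_crowns(t1$cs, t2b$cs), t1$chm, t2b$chm)
  expect_equal(mtb$status[1], "dead_or_dieback")
})

test_that("unmatched t1 crowns are resolved against the CHMs", {
  t1 <- fake_crown_set(list(c(5, 14, 5, 14), c(30, 39, 30, 39)),
                       heights = c(10, 12))
  # t2 segmentation misses both; CHM keeps crown 2 standing, crown 1 gone
  t2 <- fake_crown_set(list(c(50, 55, 50, 55)), heights = 8, survey = "t2")
  chm2 <- t1$chm
  chm2$values[5:14, 5:14] <- 0      # crown 1 vanished from the canopy
  m <- match_crowns(t1$cs, t2$cs)
  expect_equal(sort(m$unmatched_t1), c(1L, 2L))
  expect_equal(m$recruit_t2, 1L)
  mt <- classify_fate(m, t1$chm, chm2)
  expect_equal(mt$status, c("dead_or_dieback", "unresolved"))
  expect_equal(mt$decline_h[1], 1)
  expect_equal(mt$decline_h[2], 0)
})

test_that("growth increments use linear per-decade scaling and guard status", {
  t1 <- fake_crown_set(list(c(1, 10, 1, 10)), heights = 10)
  t2 <- fake_crown_set(list(c(1, 10, 1, 10)), heights = 10.18, survey = "t2")
  mt <- classify_fate(match_crowns(t1$cs, t2$cs), t1$chm, t2$chm)
  gi <- growth_increments(mt, 9)
  expect_equal(gi$delta_h_decade, 0.18 * 10 / 9, tolerance = 1e-12)
  mt$status <- "dead_or_dieback"
  expect_error(growth_increments(mt, 9), "survivors only")

  # a 12.33 m^2 crown-area gain over 9 yr is 13.7 m^2 per decade
  expect_equal(12.33 * 10 / 9, 13.7)
})

test_that("fate classes partition the t1 crown set on a full scene", {
  cfg <- scene_config(extent_m = c(250, 250), min_crown_gap_m = 4,
                      rng_seed = 17, chm_noise_sd_m = 0.1)
  tr <- place_trees(cfg)
  chm1 <- render_chm(tr, "t1"); chm2 <- render_chm(tr, "t2")
  cs1 <- two_stage_segment(chm1); cs2 <- two_stage_segment(chm2, survey = "t2")
  m <- match_crowns(cs1, cs2)
  mt <- classify_fate(m, chm1, chm2)
  expect_equal(nrow(mt), nrow(cs1$crowns))
  expect_setequal(unique(mt$status),
                  intersect(c("survived", "dead_or_dieback",
                              "ambiguous_excluded", "unresolved"),
                            unique(mt$status)))
  expect_equal(sum(table(mt$status)), nrow(cs1$crowns))
})

test_that("an identical-survey run yields all survivors and zero growth", {
  cfg <- scene_config(extent_m = c(200, 200), min_crown_gap_m = 4,
                      rng_seed = 19)
  tr <- place_trees(cfg)
  chm <- render_chm(tr, "t1")
  cs <- two_stage_segment(chm)
  mt <- classify_fate(match_crowns(cs, cs), chm, chm)
  expect_true(all(mt$status == "survived"))
  gi <- growth_increments(mt, cfg$interval_years)
  expect_identical(unique(gi$delta_h_decade), 0)
  expect_identical(unique(gi$delta_a_decade), 0)
})

test_that("fate agreement with scene truth is near-perfect when crowns are separated", {
  cfg <- scene_config(extent_m = c(400, 400), min_crown_gap_m = 5,
                      rng_seed = 23)
  tr <- place_trees(cfg)
  chm1 <- render_chm(tr, "t1"); chm2 <- render_chm(tr, "t2")
  cs1 <- two_stage_segment(chm1); cs2 <- two_stage_segment(chm2, survey = "t2")
  mt <- classify_fate(match_crowns(cs1, cs2), chm1, chm2)
  ref <- truth_labels(tr, cfg, "t1")
  rc <- xy_to_rowcol(chm1, mt$x, mt$y)
  tid <- ref[rc]
  ok <- tid > 0
  truth_died <- tr$died[match(tid[ok], tr$id)]
  resolved <- mt$status[ok] %in% c("survived", "dead_or_dieback")
  agree <- resolved & ((mt$status[ok] == "dead_or_dieback") == truth_died)
  expect_gte(mean(agree), 0.99)
})

test_that("raising the decline threshold never increases the dead count", {
  cfg <- scene_config(extent_m = c(250, 250), min_crown_gap_m = 4,
                      rng_seed = 29, chm_noise_sd_m = 0.1)
  tr <- place_trees(cfg)
  chm1 <- render_chm(tr, "t1"); chm2 <- render_chm(tr, "t2")
  cs1 <- two_stage_segment(chm1); cs2 <- two_stage_segment(chm2, survey = "t2")
  m <- match_crowns(cs1, cs2)
  deaths <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), function(th)
    sum(classify_fate(m, chm1, chm2, th)$status == "dead_or_dieback"),
    numeric(1))
  expect_true(all(diff(deaths) <= 0))
})

test_that("mortality rate conventions are mutually consistent", {
  mr <- mortality_rate(3801, 42213, 9)
  expect_equal(mr$raw_pct, 100 * 3801 / 42213)
  expect_equal(mr$linear_pct_decade, mr$raw_pct * 10 / 9)
  expect_equal(mr$compound_pct_decade,
               100 * (1 - (1 - 3801 / 42213)^(10 / 9)))
  expect_lt(mr$compound_pct_decade, mr$linear_pct_decade)
})
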