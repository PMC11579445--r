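test_that("stem-diameter allometry evaluates the published form", {
  # 0.519 * 50^0.890 * 1.002, checked against independent scalar evaluation
  expect_equal(estimate_dbh(10, 5), 16.9088, tolerance = 1e-4)
  expect_equal(estimate_dbh(1, 1), 0.519 * 1.002)
  # doubling H*CD multiplies DBH by 2^0.890
  expect_equal(estimate_dbh(20, 5) / estimate_dbh(10, 5), 2^0.890)
  expect_error(estimate_dbh(-1, 5), "positive")
  expect_error(estimate_dbh(10, 0), "positive")
})

test_that("biomass allometry evaluates the published form and is monotone", {
  expect_equal(estimate_agb(20), 174.57, tolerance = 1e-4)
  expect_equal(estimate_agb(1), 0.133 * 1.067)
  d <- seq(1, 80, by = 0.5)
  expect_true(all(diff(estimate_agb(d)) > 0))
  expect_error(estimate_agb(0), "positive")
  # composition is strictly increasing in both crown dimensions
  expect_true(all(diff(estimate_agb(estimate_dbh(seq(5, 20, 1), 8))) > 0))
  expect_true(all(diff(estimate_agb(estimate_dbh(10, seq(2, 15, 1)))) > 0))
})

test_that("size metric is the plain product of height and crown diameter", {
  expect_equal(size_metric(10, 5), 50)
  expect_equal(size_metric(1, 1), 1)
  s <- size_metric(runif(50, 5, 20), runif(50, 2, 15))
  expect_equal(order(s), order(estimate_dbh(rep(1, 50), s)))  # rank-identical
})

fake_matched <- function(status, H1, CD1, H2 = H1, CD2 = CD1) {
  n <- length(status)
  data.frame(id_t1 = seq_len(n), status = status,
             H_t1 = H1, CD_t1 = CD1, A_t1 = pi * (CD1 / 2)^2,
             H_t2 = H2, CD_t2 = CD2, A_t2 = pi * (CD2 / 2)^2,
             x = runif(n, 0, 100), y = runif(n, 0, 100))
}

test_that("biomass change zeroes the dead and excludes the unresolved", {
  tr <- fake_matched(c("survived", "dead_or_dieback", "unresolved",
                       "ambiguous_excluded"),
                     H1 = c(10, 9.37, 10, 10), CD1 = c(5, 5, 5, 5),
                     H2 = c(10, NA, NA, NA), CD2 = c(5, NA, NA, NA))
  out <- agb_change(tr, 9)
  expect_equal(out$delta_agb_decade[1], 0)
  expect_equal(out$delta_agb_decade[2], -out$agb_t1[2] * 10 / 9)
  expect_true(all(is.na(out$delta_agb_decade[3:4])))
  # a dead tree with 117 kg in 2012 loses 130 kg per decade
  expect_equal(-117 * 10 / 9, -130)

  grown <- agb_change(fake_matched("survived", 10, 5, 10, 6), 9)
  expect_gt(grown$delta_agb_decade, 0)
})

test_that("log binning spans the range with equal log-width bins", {
  size <- c(10, 15, 20, 30, 60, 100, 200, 400, 600, 800, 1000)
  b <- bin_trees(size, "log_equal_width", 10)
  expect_equal(b$edges[1], 10)
  expect_equal(b$edges[11], 1000)
  expect_equal(b$edges[2], 10 * (1000 / 10)^(1 / 10))  # first cut at 10^1.2
  expect_equal(diff(log(b$edges)), rep(log(100) / 10, 10))
  expect_equal(b$bin[1], 1L)
  expect_equal(b$bin[length(size)], 10L)  # right edge inclusive, last bin
  expect_error(bin_trees(rep(7, 20), "log_equal_width"), "degenerate")
  expect_error(bin_trees(c(1, 2), "log_equal_width", 10), "at least")
})

test_that("percentile binning gives equal counts with deterministic ties", {
  set.seed(8)
  size <- rlnorm(1005, 4, 0.8)
  b <- bin_trees(size, "percentile", 10)
  counts <- table(b$bin)
  expect_equal(length(counts), 10)
  expect_lte(diff(range(counts)), 1)

  # 4221 trees per decile when 42210 trees are split ten ways
  expect_equal(42210 / 10, 4221)

  tied <- c(rep(5, 30), rep(9, 10))
  bt <- bin_trees(tied, "percentile", 4)
  expect_lte(diff(range(table(bt$bin))), 1)
  expect_identical(bt$bin, bin_trees(tied, "percentile", 4)$bin)
  expect_error(bin_trees(rep(7, 20), "percentile"), "degenerate")
})

test_that("size-class rates recover proportions, CIs and exact accounting", {
  set.seed(21)
  n <- 1000
  status <- rep("survived", n)
  status[sample(n, 100)] <- "dead_or_dieback"
  H1 <- runif(n, 5, 20); CD1 <- runif(n, 3, 15)
  tr <- fake_matched(status, H1, CD1,
                     H2 = ifelse(status == "survived", H1 + 0.2, NA),
                     CD2 = ifelse(status == "survived", CD1 + 0.3, NA))
  tr <- agb_change(tr, 9)
  surv <- tr$status == "survived"
  tr$delta_h_decade <- NA_real_; tr$delta_a_decade <- NA_real_
  tr$delta_h_decade[surv] <- (tr$H_t2 - tr$H_t1)[surv] * 10 / 9
  tr$delta_a_decade[surv] <- (tr$A_t2 - tr$A_t1)[surv] * 10 / 9
  bins <- bin_trees(size_metric(tr$H_t1, tr$CD_t1), "percentile", 10)
  sc <- size_class_rates(tr, bins, area_ha = 10)

  # saturated binomial GLM equals the raw proportion per class
  d <- data.frame(died = as.integer(tr$status == "dead_or_dieback"),
                  bin = factor(bins$bin))
  glm_fit <- glm(died ~ bin - 1, family = binomial(), data = d)
  p_glm <- unname(plogis(coef(glm_fit)))
  expect_equal(sc$p_mortality, p_glm, tolerance = 1e-6)

  # accounting identities hold to machine precision
  expect_equal(sc$net_mg_ha_decade,
               sc$gains_mg_ha_decade + sc$losses_mg_ha_decade)
  tot <- attr(sc, "totals")
  expect_equal(tot$net_mg_ha_decade,
               tot$gains_mg_ha_decade + tot$losses_mg_ha_decade)
  expect_equal(sum(sc$stock_fraction_pct), 100)
  expect_equal(tot$agb_stock_mg_ha, sum(tr$agb_t1) / 1000 / 10)

  # all-survivor class keeps a proper (Wilson) interval at p = 0
  tr0 <- tr; tr0$status <- "survived"
  tr0$delta_h_decade <- 0.2; tr0$delta_a_decade <- 1
  sc0 <- size_class_rates(tr0, bins, area_ha = 10)
  expect_true(all(sc0$p_mortality == 0))
  expect_true(all(sc0$p_mort_hi > 0 & sc0$p_mort_hi < 0.1))

  # percentile-mode stocks rise with bin index (AGB monotone in size)
  expect_true(all(diff(sc$agb_stock_mg_ha) > 0))
})

test_that("binned mortality recovers the generating logistic curve", {
  cfg <- scene_config()
  tt <- simulate_tree_table(10000, cfg, seed = 3)
  tt$status <- ifelse(tt$died, "dead_or_dieback", "survived")
  tt$H_t1 <- tt$H_t1; tt$CD_t1 <- tt$CD_t1
  tt$A_t1 <- pi * (tt$CD_t1 / 2)^2
  tt$H_t2 <- tt$H_t1; tt$CD_t2 <- tt$CD_t1; tt$A_t2 <- tt$A_t1
  tt$delta_h_decade <- ifelse(tt$died, NA, tt$delta_h_decade)
  tt$delta_a_decade <- ifelse(tt$died, NA, tt$delta_a_decade)
  tt <- agb_change(tt, 9)
  bins <- bin_trees(tt$size, "log_equal_width", 10)
  sc <- size_class_rates(tt, bins, area_ha = 100)
  for (b in which(sc$n_trees >= 200)) {
    sel <- bins$bin == b
    p_true <- mean(tt$p_death[sel])
    expect_gte(p_true, sc$p_mort_lo[b] - 0.02)
    expect_lte(p_true, sc$p_mort_hi[b] + 0.02)
  }
})

test_that("the population summary reproduces closed-form sums", {
  tr <- fake_matched(rep(c("survived", "dead_or_dieback"), c(18, 2)),
                     H1 = seq(5, 24, 1), CD1 = seq(3, 12.5, 0.5))
  tr$H_t2[tr$status == "dead_or_dieback"] <- NA
  tr <- agb_change(tr, 9)
  surv <- tr$status == "survived"
  tr$delta_h_decade <- ifelse(surv, 0.2, NA)
  tr$delta_a_decade <- ifelse(surv, 10, NA)
  ds <- demographic_summary(tr, area_ha = 2, interval_years = 9)
  expect_equal(ds$n_tracked, 20)
  expect_equal(ds$mortality_raw_pct, 10)
  expect_equal(ds$mortality_linear_pct_decade, 10 * 10 / 9)
  expect_equal(ds$agb_stock_t1_mg_ha, sum(tr$agb_t1) / 1000 / 2)
  expect_equal(ds$gains_mg_ha_decade + ds$losses_mg_ha_decade,
               ds$net_mg_ha_decade)
  # top decile of 20 trees = the 2 largest by H x CD
  sz <- size_metric(tr$H_t1, tr$CD_t1)
  top2 <- order(-sz)[1:2]
  expect_equal(ds$top_decile_stock_pct,
               100 * sum(tr$agb_t1[top2]) / sum(tr$agb_t1))
})
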