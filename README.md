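# crowndynamics

Tracking the demography of individual trees — height growth, crown
expansion, dieback and mortality — from repeat airborne laser scanning
(ALS) surveys of open-canopy woodland.

Permanent field plots capture tree demography precisely but cover tiny
areas. Repeat ALS flights produce canopy height models (CHMs) over whole
landscapes; in open woodland dominated by large single-stemmed trees, the
crowns of individual canopy trees are clearly resolved at 0.5-m resolution,
so demographic rates can be estimated tree by tree over thousands of
hectares. `crowndynamics` implements that analysis end to end for R users
working with paired CHMs: ecologists and remote-sensing scientists who want
size-resolved growth, mortality and biomass budgets, and the landscape
drivers behind them.

## What the package does

1. **Crown segmentation** (`two_stage_segment`). Seed-based region growing
   in the *dalponte2016* family: local maxima of the CHM detected with an
   allometric search window whose diameter follows crown width,
   w(h) = c·h^d + floor, then height-descending region growth with the two
   classical thresholds (a pixel joins a crown iff its height exceeds
   `th_seed`·seed height and `th_cr`·current region mean). The segmentation
   runs in two stages — a broad window that delineates large crowns without
   oversegmenting them, then a small window over the unclaimed remainder to
   recover small trees — and keeps crowns with H > 4 m and area > 9 m².
   `benchmark_segmentation` scores a segmentation against reference crowns
   (correct / oversegmented / omitted, IoU, precision, recall, F1 at
   IoU > 50%).
2. **Crown matching and fate** (`match_crowns`, `classify_fate`). A 2012
   crown matches a 2021 crown when it contains the 2021 centroid; crowns
   containing two or more centroids of the other survey are removed as
   probable oversegmentations. Matched trees that lost ≥ 30% of height
   and/or crown area — and unmatched 2012 crowns whose in-polygon CHM
   maximum dropped ≥ 30% — are classed as dead or severe dieback.
3. **Growth and biomass** (`growth_increments`, `estimate_dbh`,
   `estimate_agb`, `agb_change`, `size_class_rates`). Per-decade increments
   (×10/T for a T-year interval); stem diameter from crown dimensions,
   DBH = 0.519·(H·CD)^0.890·CF, and eucalypt aboveground biomass
   AGB = 0.133·DBH^2.375·CF; dead trees lose all biomass. Rates and
   gain/loss/net biomass budgets are resolved across ten size classes of
   H×CD (equal log-width or percentile bins).
4. **Covariates and drivers** (`compute_twi`, `neighbourhood_height`,
   `pulse_density_difference`, `fit_gam`). Topographic wetness
   TWI = ln(a / tan β) from sink-filled DTMs with multiple-flow-direction
   routing; mean CHM height in a 25-m buffer around each crown as a
   competition proxy; pulse-density difference between surveys as a
   nuisance covariate. GAMs (via mgcv, REML) model each rate as a penalized
   smooth in tree size plus standardized linear terms, with conditional
   prediction curves and a residual Moran's I correlogram.
5. **Landscape maps** (`hectare_grid`, `canopy_cover`, `canopy_volume`,
   `delta_metrics`, `aggregate_trees`). Tree-level rates and CHM-level
   structural change (Δcover above 4 m, Δvolume) aggregated on a 1-ha grid.
6. **Synthetic scenes** (`scene_config`, `place_trees`, `render_chm`, …).
   A generator of paired CHMs, terrain, pulse-density fields and
   ground-truth tree tables with the statistical structure the analysis
   assumes, so the whole pipeline is testable without survey data.

Rasters are read and written as single-band float GeoTIFFs
(`read_geotiff` / `write_geotiff`); crowns export to CSV and GeoJSON.

## Worked example

A 9-ha synthetic woodland, 9 years between surveys:

```r
library(crowndynamics)

cfg <- scene_config(extent_m = c(300, 300), min_crown_gap_m = 4,
                    chm_noise_sd_m = 0.1, rng_seed = 1)
truth    <- place_trees(cfg)
chm_2012 <- render_chm(truth, "t1")
chm_2021 <- render_chm(truth, "t2")

crowns_2012 <- two_stage_segment(chm_2012, survey = "t1")
crowns_2021 <- two_stage_segment(chm_2021, survey = "t2")
crowns_2012
#> <crown_set> 198 crowns (survey t1)

trees <- classify_fate(match_crowns(crowns_2012, crowns_2021),
                       chm_2012, chm_2021)
table(trees$status)
#> dead_or_dieback        survived
#>              16             182
```

Growth, biomass and a driver model:

```r
surv <- trees$status == "survived"
trees[surv, c("delta_h_decade", "delta_a_decade")] <-
  growth_increments(trees[surv, ], 9)[, c("delta_h_decade", "delta_a_decade")]
trees <- agb_change(trees, 9)
summ <- demographic_summary(trees, area_ha = 9, interval_years = 9)
cat(sprintf(
  "mortality %.1f%%/decade | height growth %.2f m/decade | crowns %+.1f m2/decade
AGB %.1f Mg/ha; gains %+.2f, losses %+.2f, net %+.2f Mg/ha/decade",
  summ$mortality_linear_pct_decade, summ$mean_dh_m_decade,
  summ$mean_da_m2_decade, summ$agb_stock_t1_mg_ha, summ$gains_mg_ha_decade,
  summ$losses_mg_ha_decade, summ$net_mg_ha_decade))
#> mortality 9.0%/decade | height growth 0.35 m/decade | crowns +12.8 m2/decade
#> AGB 20.7 Mg/ha; gains +3.42, losses -1.26, net +2.16 Mg/ha/decade

twi <- compute_twi(generate_dtm(cfg))
cov <- tree_covariates(trees, crowns_2012, chm_2012, twi,
                       render_pulse_density(cfg, "t1"),
                       render_pulse_density(cfg, "t2"))
fit_gam(cov, "delta_h_decade")
#> <demog_gam> delta_h_decade ~ s(size) + twi + neigh + pd  [gaussian-identity], n = 182
#>          term estimate     se statistic  p_value
#> 1 (Intercept)  0.34709 0.0170    20.391 2.60e-48
#> 2       twi_z  0.09759 0.0171     5.708 4.73e-08
#> 3     neigh_z  0.02963 0.0177     1.676 9.54e-02
#> 4        pd_z  0.00434 0.0175     0.249 8.04e-01
#> smooth edf: 1.16
```

Trees grow faster in wetter positions (positive standardized TWI
coefficient); the pulse-density term is indistinguishable from zero on a
scene where the generator's pulse effect is small relative to noise. On
9 ha of simulated stand the mortality, crown-expansion and biomass numbers
come out in the range observed in real semi-arid eucalypt woodland
(~1%/yr mortality, ~13 m² per decade crown expansion, ~20–30 Mg/ha
standing biomass).

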