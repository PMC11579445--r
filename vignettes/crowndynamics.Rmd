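---
title: "Methods: individual-tree demography from repeat ALS canopy height models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-tree demography from repeat ALS canopy height models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crowndynamics` estimates tree-level demographic rates from a pair of
co-registered canopy height models (CHMs) taken years apart over the same
open woodland. This vignette is the package's account of the methods: the
models and their assumptions, the parameters that matter, the numerical
conventions, and what the synthetic test scenes do and do not demonstrate.

## Scope and assumptions

The pipeline assumes the setting in which crown-level change detection from
CHMs works best: an open canopy of relatively large, single-stemmed trees on
near-flat terrain, imaged at 0.5-m CHM resolution with crowns spanning many
pixels. Under a closed or multi-layered canopy, segmentation and matching
errors would dominate, and none of the accuracy properties exercised by the
test suite would transfer. Two further structural assumptions are baked in:
each tree produces a single dominant CHM local maximum, and a tree that dies
or loses its crown leaves a detectable height collapse inside its old crown
polygon.

## Crown segmentation

Segmentation is seed-plus-region-growing. A pixel seeds a crown when it is
the strict maximum of a circular window whose diameter follows a
crown-width/height allometry, `w(h) = c·h^d + floor` (defaults `c = 1.2`,
`d = 0.95`, `floor = 1.5` m, matching the synthetic generator's allometry;
for real data these should be re-fitted to locally measured crowns). Regions
then grow from the seeds down a single global height-descending queue; a
candidate pixel joins its region iff it is unclaimed, taller than
`th_seed`×seed height, taller than `th_cr`×the region's running mean height,
and within an allometric maximum radius of the seed. Defaults
`th_seed = 0.45` and `th_cr = 0.55` are the canonical defaults of this
algorithm family; they are exposed in `segmentation_params()` because no
universal values exist.

The two-stage arrangement addresses a known failure mode: with a window
small enough to find small trees, large crowns fragment into several
segments (oversegmentation). Pass 1 therefore uses the full allometric
window (`broad_window_scale = 1`) and delineates large crowns cleanly; its
claimed pixels are masked to nodata; pass 2 reruns detection and growth at
half the window (`small_window_scale = 0.5`) on the remainder, recovering
small trees that sat inside a large tree's search window. Crowns not
strictly taller than 4 m or not strictly larger than 9 m² are dropped — the
strict inequalities are deliberate and tested.

Determinism is part of the contract. Ties between equal-height pixels in
seed detection go to the first pixel in column-major scan order (flagged in
the output); the growth queue orders by height descending, then pixel index,
then seed id. The test suite holds the C++ implementation to exact label
equality with an independently written R reference grower over one hundred
randomized canopies, so the documented order is the implemented order.

Crowns are represented as label grids; "polygons" are exact pixel-boundary
tracings, so crown area is exactly pixel count × pixel area and
intersection-over-union computations in the benchmark are exact integer
arithmetic. No boundary smoothing is applied.

## Matching, fate, growth

A first-survey crown matches a second-survey crown when it contains the
latter's centroid; containment is evaluated on the label grid (the pixel the
centroid falls in), which gives a deterministic, boundary-exclusive rule.
Any crown in either survey containing two or more centroids from the other
survey is treated as a probable oversegmentation and every pairing involving
it is discarded (`ambiguous_excluded`); such trees contribute to no rate.

Matched trees that declined by ≥ 30% (boundary inclusive) in height *or*
crown area are classed `dead_or_dieback`; the same threshold applied to the
change of the in-polygon CHM maximum resolves the unmatched 2012 crowns.
Unmatched crowns whose canopy height did not collapse are `unresolved` —
presumed segmentation omissions — and are likewise excluded rather than
counted as survivors. Height is the maximum CHM value in the crown polygon
(the field convention); the mean-CHM variant is computed and stored
alongside because the two can disagree for ragged crowns.

Growth increments are linear per-decade rescalings, `Δ × 10/T` for a
T-year interval. For mortality the "% per decade" convention is genuinely
ambiguous for T ≠ 10, so `mortality_rate()` reports three variants side by
side: the raw fraction, the linear rescaling, and the compound form
`1 − (1 − m)^{10/T}`. They differ by a few tenths of a percentage point at
woodland mortality levels.

## Allometry and biomass accounting

Stem diameter comes from crown dimensions via
`DBH = 0.519·(H·CD)^0.890·1.002` (cm) and aboveground biomass via
`AGB = 0.133·DBH^2.375·1.067` (kg), both published allometries for
Australian woodland trees with Baskerville back-transformation corrections.
The `(H·CD)^exp` form (rather than `H·CD^exp`) follows the source framework
of the DBH model. Dead trees are assumed to lose all biomass; ambiguous and
unresolved trees are excluded, never zeroed. Gains are the summed biomass
change of survivors, losses the summed (negative) change of the dead, and
`net = gains + losses` holds to machine precision per size class and in
aggregate — an accounting identity the tests assert rather than a result.

Size classes are deciles of `H × CD` either in equal log-width bins (the
size distribution is strongly right-skewed) or percentile bins (equal
counts, for comparable per-class biomass budgets). Percentile ties are
resolved by first occurrence, deterministically; per-class mortality is the
saturated binomial GLM on the class factor, identical to the raw proportion,
with logit-scale Wald intervals and Wilson intervals in all-dead/all-alive
classes.

## Terrain and competition covariates

TWI is `ln(a / tan β)` at 5-m resolution: the DTM is sink-filled by
priority flood (with a 10⁻⁶ m epsilon gradient across filled flats so
routing cannot stall), flow is routed by multiple flow directions with
fractions proportional to slope (D8 is available and used as the test
oracle), specific catchment area uses the cell size as contour width, and
slope is floored at `tan β = 0.001` to keep flat cells finite. Flow
accumulation conserves contributing area exactly; the suite checks
conservation to 10⁻⁹ and equality with a dense linear-algebra oracle
(`acc = (I − Wᵀ)⁻¹·1`) on small grids.

Neighbourhood competition is the mean CHM height within a 25-m buffer
around the crown perimeter, computed by an exact Euclidean distance
transform on a cropped window. The focal crown's own pixels are excluded by
default (the buffer is an annulus); the inclusive variant is a switch, since
either reading of "a buffer around the perimeter" is defensible. Crowns
whose buffer is clipped by the raster edge are flagged rather than dropped.
Pulse-density difference (t2 − t1) is sampled at the crown centroid.

## Driver models

Each demographic rate is modelled as a GAM: a penalized cubic regression
spline in tree size (basis dimension 10, smoothing chosen by REML) plus
linear terms for TWI, neighbourhood height and pulse-density difference,
each standardized to mean 0, sd 1 with the constants stored in the fit, so
raw-scale effects and the "pulse difference = 0" prediction profile are
recovered exactly. Growth models are Gaussian; mortality is binomial-logit.
Complete cases only; separation and constant covariates raise errors rather
than warnings. Forcing the smoothing parameter to a very large value
collapses the spline to its linear null space, and the fit then agrees with
OLS — a closed-form anchor the tests exercise.

Residual spatial autocorrelation is summarised as a binned Moran's I
correlogram with a permutation envelope (199 permutations, seeded); a
single-bin correlogram equals global Moran's I, cross-checked against
`ape::Moran.I`.

## The synthetic scene generator

The generator exists so that every stage has a ground truth. Its defaults
describe the study conditions of semi-arid old-growth eucalypt woodland:
22 stems ha⁻¹; heights lognormal around ~11 m truncated to 4–22 m; crown
diameters `CD = 1.2·H^0.95` with lognormal scatter (sd 0.12), giving mean
crown areas near 125 m²; crowns placed as a hard-core process (discs
separated by a configurable gap) by largest-first dart throwing — unordered
dart throwing stalls well short of 22 stems ha⁻¹ once large crowns are
down, while placing trees in decreasing size order reaches the target
density and remains a hard-core pattern; a tilted-plane DTM carved by a
sinuous drainage channel; survey pulse densities 21.4 and 23.6 pulses m⁻²;
a 9-year interval.

Demography follows the size trends reported for such woodlands: height
growth decays with size (0.5 → 0.06 m per decade, e-folding scale 60 m² of
`H·CD`, which also reproduces a population mean of ~0.2–0.4 m per decade
depending on the realized size distribution), crown expansion saturates
upward (7 → 16.5 m² per decade), and mortality is logistic, declining with
log size and wetness and rising with crowding (roughly 20%/interval for the
smallest trees, 7–8% for large ones). A quarter of dying trees undergo
severe dieback (height and crown radius halved) instead of vanishing,
exercising the matched-decline path of the classifier as well as the
disappearance path.

Crowns render as paraboloid caps, `h(r) = H − (H − 0.4·H)(r/R)²`, chosen
because a paraboloid has exactly one CHM local maximum — the segmentation
model's core assumption. CHM noise is additive Gaussian (0.1 m where
enabled), clipped at zero. This is a stand-in: real eucalypt crowns have
within-crown texture, occlusion and pit artefacts that no parameter here
calibrates. Consequently the suite's near-perfect recovery rates (F1 and
recall ≥ 0.95 on separated noise-free scenes, ≥ 0.85 with noise; ≥ 99% fate
agreement) certify the *machinery* — ordering, thresholds, bookkeeping —
not field accuracy. On real CHMs, published figures for this algorithm
family (F1 near 0.9 in open canopy) are the realistic expectation, and the
crown-width allometry in the search window must be locally re-fitted.

## Numerical conventions and degenerate inputs

* Rasters: row 1 is the northern edge; points on a pixel's left/top edge
  belong to that pixel; a raster's outer right/bottom edge is clamped
  inward. GeoTIFF output is float64 by default so round trips are
  bit-exact; nodata is −9999 via the GDAL_NODATA convention.
* Hectare cells anchor at the raster origin; partial edge cells keep their
  true pixel counts and an `edge` flag; cells that are fully nodata (or
  majority-masked) yield `NA`, never 0.
* Empty seed lists, empty crown sets and empty pairings are legal and
  propagate as empty results; an empty *reference* set in benchmarking is
  an error because the benchmark is undefined.
* Degenerate size distributions (all sizes equal) make both binning modes
  error; percentile ties are split deterministically by first occurrence.
* All generators and permutation tests derive their randomness from
  explicit seeds; the same seed gives bit-identical output, and the
  acceptance script threads a single `--seed` through every stage.

## Problem sizes

The test suite and acceptance script run on scenes of 2.25–25 ha
(150–500 m squares, CHMs up to 1000×1000 pixels, ~70–550 trees), 100
randomized oracle canopies up to 100×100 pixels, and model fits at
n = 2000–10000 with 50-replicate coverage checks at n = 5000 — sizes
chosen so the whole suite completes in well under a minute per criterion
while every property is exercised at meaningful scale. The pipeline itself
is linear in pixels and trees; a full 2500-ha survey pair at 0.5 m is
within reach of the same code path, with the region-growing and
distance-transform kernels in C++.

## Known limitations

* No reprojection: all rasters must already share a metric, axis-aligned
  grid (alignment is checked, never corrected beyond integer-pixel
  clipping).
* Matching is two-epoch and rule-based; probabilistic or multi-epoch
  tracking is out of scope. Recruitment (crowns present only in the second
  survey) is counted but never converted to a rate, because trees can pass
  the size threshold and die within one interval, biasing any such
  estimate low.
* Allometric uncertainty is not propagated; biomass totals inherit the
  full error of the two published equations.
* The TWI implementation follows standard MFD conventions; other software
  differs in upslope-area and contour-width details, so absolute TWI
  values are comparable only within one implementation.
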