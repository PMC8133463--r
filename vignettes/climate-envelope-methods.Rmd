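---
title: "Climate-envelope range modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climate-envelope range modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climenvelope)
```

## The problem

Some range-restricted tropical birds occupy climate envelopes bounded by
hard upper limits: above a ceiling in maximum temperature of the warmest
month (around 30–35 °C) and in dry-season precipitation (around 50–70 mm)
the species simply do not occur. For such species, a climate-only species
distribution model (SDM) fitted to presence/absence data can describe the
current range well, and projecting the fitted envelope over future climate
grids gives the *maximum potential* range under each scenario — an upper
bound, since habitat and land use impose further limits.

`climenvelope` implements this workflow end to end:

1. **Occurrence assembly** — presences, absences at the midpoints of walked
   transects without detections, and uniform pseudo-absences excluded from a
   buffer around every presence.
2. **Model suite** — five algorithms (GLM, GAM, MaxEnt-equivalent, boosted
   regression trees, random forest) behind a single
   fit / predict / response-curve contract.
3. **Spatially blocked validation** — leave-one-radial-segment-out
   cross-validation, pooled AUC-ROC, and delta-AUC variable importance.
4. **Thresholding and projection** — max-kappa binarisation under current
   conditions, projection over GCM × RCP × year grids, latitude-corrected
   areas, and the percent-of-current-range-left summary table.
5. **A synthetic world** — a generator producing climate grids, true
   occupancy, presences and transects with the statistical structure the
   analysis assumes, so every stage is testable offline.

## The synthetic world

The generator (`synthetic_world_config()`, `generate_climate_grid()`)
builds five bioclim covariate surfaces on a regular lon/lat grid. Two of
them govern occupancy:

* maximum temperature of the warmest month rises radially away from a cool
  core (default 28 °C at the core, +3.5 °C per degree of distance);
* dry-quarter precipitation also rises away from the core, but along an
  *anisotropic, rotated* distance field. This is deliberate: if both fields
  were radial about the same centre they would be nearly collinear, and no
  additive model could attribute the occupancy decline between temperature
  and precipitation — parameter recovery and delta-AUC importance would be
  ill-posed by construction. The rotation keeps the core cool *and* dry
  while giving the two covariates distinct spatial footprints (correlation
  ≈ 0.65 rather than ≈ 0.99).

The other three covariates (temperature seasonality, annual range,
wet-quarter precipitation) are nuisance fields: mild linear gradients plus
smoothed Gaussian noise, with no role in occupancy. All five bands receive
spatially autocorrelated noise (white noise smoothed with a Gaussian kernel
of `field_smoothing_scale` cells, rescaled to the per-band `noise_sd`), so
lag-1 spatial autocorrelation exceeds 0.5 in every band, as in real climate
grids.

True occupancy is the product of two logistic threshold responses,

$$p(\text{cell}) \;=\;
  \operatorname{logit}^{-1}\!\Big(\frac{T_0 - T}{s_T}\Big)\cdot
  \operatorname{logit}^{-1}\!\Big(\frac{P_0 - P}{s_P}\Big),$$

with defaults $T_0 = 33$ °C, $s_T = 1$ °C, $P_0 = 60$ mm, $s_P = 8$ mm —
the middles of the 30–35 °C and 50–70 mm ranges the envelope is meant to
recover. A soft product rather than a hard step keeps likelihood-based
fitters well behaved while leaving the thresholds recoverable.

Presences are drawn with probability proportional to occupancy and
jittered within their cell. Transects are placed by stratified random
sampling over a macro-grid (so some fall outside the core), run 1 km in a
uniform random direction, and detect with probability
`detection_prob × mean occupancy along the transect`.

Scale: the reference workflow uses 30-arc-second grids; the synthetic
default is 0.05° (~5.5 km) over a 4° × 3° window (4,800 cells) so the full
pipeline runs in seconds. Nothing downstream depends on the absolute cell
count; areas are computed per cell with the cosine-latitude correction
regardless of resolution. Units are plain °C and mm (the ×10 integer
encoding used by some climate archives is deliberately not reproduced).

What a green test does **not** establish: the synthetic world has no
observer bias, no spatial clustering of survey effort beyond the stratified
transects, additive (not pattern-shifting) climate change, and noise-free
detection of presences. Results on it validate the machinery, not any
ecological claim.

## The model suite

All five algorithms consume the same feature table (five covariates,
binary response) and emit probabilities in [0, 1]:

* **GLM** — binomial regression with linear + quadratic terms per z-scored
  covariate. The quadratic permits the interior optimum a climate envelope
  implies.
* **GAM** — binomial additive model with penalised thin-plate smooths
  (`mgcv`, basis dimension `k = 5`, REML), z-scored covariates.
* **MAXENT** — the maximum-entropy presence/background model in its
  penalised-regression form: an L1-regularised binomial regression
  (`glmnet`) of presences against the zero-response rows, with background
  weights scaled so total background weight equals total presence weight,
  over linear, quadratic and hinge features (5 knots per covariate per
  direction at training quantiles). The penalty is chosen by seeded 5-fold
  `cv.glmnet` (`lambda.min`). This statistical identity replaces the
  reference Java implementation.
* **BRT** — logistic gradient boosting over depth-3 regression trees grown
  by an in-package CART engine (Rcpp), with Newton leaf updates, learning
  rate 0.01, bag fraction 0.5, and the iteration count chosen on a seeded
  20 % stratified internal holdout (cap 500 trees). No boosting package is
  available in the build environment, so the engine is implemented here in
  the standard formulation.
* **RF** — a random forest from the same CART engine: 500 trees on
  bootstrap resamples, `mtry = 2`, unlimited depth, minimum node size 5;
  the reported probability is the fraction of trees voting presence.

Degenerate inputs: a single-class response always errors; constant
covariates collapse GLM/GAM/BRT/RF to a constant prediction (the base rate
through each link/vote construction) while MAXENT errors, because the lasso
has no non-constant feature to select. Both behaviours satisfy the
fit contract and are asserted in the tests.

Response curves hold the other four covariates at their training means (a
choice: medians or presence-weighted means would be defensible too) and
span the focal covariate's training range. `response_halfmax()` reports the
covariate value of the curve's **final descent** through half of its
maximum: for a monotone envelope this is the unique crossing, and for
wiggly lasso/tree fits the last crossing is the quantity with the
threshold interpretation (the level above which suitability stays low).

## Spatially blocked validation

Records are assigned to `k = 5` equal-angle radial sectors about the
presence centroid by the planar bearing of each point (sector 0 starts due
east; the offset is configurable because the true sector placement in the
motivating study is unrecoverable). Pseudo-absences participate in folds by
their own bearing. Each algorithm is refitted `k` times leaving one sector
out; the held-out predictions are pooled and scored with a single AUC
(not averaged per fold). AUC is the Mann–Whitney concordance with ties
counting one half, computed by midranks — exactly the all-pairs
enumeration, which the tests verify against a brute-force oracle.

Variable importance refits the model with each covariate left out in turn,
over the same folds: `delta_auc = auc_full − auc_without`, standardised to
shares by dividing by the summed deltas. Negative deltas are reported
as-is; shares are `NA` whenever the sum is not positive, since the
standardisation presumes a positive total. Algorithms advance to
importance analysis and projection only if their pooled blocked AUC
exceeds 0.6 (configurable), applied strictly before any importance
computation.

## Thresholding, areas, scenarios

`max_kappa_threshold()` evaluates Cohen's kappa at every distinct predicted
value plus 0 and 1 (comparator `>=`), returning the smallest maximising
threshold. Thresholds are derived **once, under current conditions**, and
transferred unchanged to every future scenario — the range table asserts
this.

Cell areas use the cosine-latitude rectangle approximation
$(rK)(rK\cos\phi)$ with $K = 111.32$ km/degree; at tropical latitudes this
is within 0.3 % of the exact spherical value (the tests check a
30-arc-second equatorial cell against the spherical-cap formula
$R^2\,\Delta\lambda\,(\sin\phi_2-\sin\phi_1)$).

Future grids are the current grid plus per-band additive offsets, one set
per GCM. The bundled `gcm_delta_table()` ships six *synthetic* GCM delta
sets per RCP and year: mean warming follows the best-estimate global
surface-temperature ranges associated with the four pathways (interpolated
to 2050/2070; the lowest pathway peaks by mid-century, so its 2070 warming
equals its 2050 warming), spread across GCMs by fixed multipliers from 0.7
to 1.4, with small per-GCM dry-season precipitation offsets. These are
stand-ins with the right orders of magnitude, not any real GCM's output.

The range table reports, per RCP × year: the suitable area of every
(algorithm × GCM) member, their mean/min/max, and
`percent_left = round(100 × mean_future / mean_current)` (half-up, matching
the integer precision such tables are printed at). The "current simulated
range" is the mean over selected algorithms of current binarised areas.
Member min/max pool algorithms and GCMs jointly, and the column is named
accordingly, since finer groupings are equally defensible.

## Reproducibility

Every stochastic stage takes an explicit seed; the pipeline fans a single
run seed out to stage seeds through `derive_seed()` (a fixed integer hash
of the stage name, kept below 2³¹), so stages are independently
reproducible and two runs with the same configuration are byte-identical —
this is tested. The run manifest records the seed, a configuration hash and
package/R versions.

## Known limitations

* No dispersal constraints, habitat masking or abundance modelling:
  projections are maximum potential ranges.
* No detectability model for transects (non-detections are treated as
  absences, as in the motivating workflow).
* No spatial-autocorrelation-aware variance for AUC; the blocked design
  mitigates, but does not eliminate, optimism from residual autocorrelation.
* The MaxEnt equivalence is the penalised-regression form; feature classes
  beyond linear/quadratic/hinge (product, threshold) are not implemented.
* Grid I/O is plain CSV with metadata headers; no GeoTIFF support in this
  build environment.
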