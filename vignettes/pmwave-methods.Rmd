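---
title: "Hourly PM2.5 surfaces from gap-filled satellite AOD: models and methods"
author: "pmwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hourly PM2.5 surfaces from gap-filled satellite AOD: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Ground monitors measure PM2.5 accurately but sparsely; geostationary
satellites observe aerosol optical depth (AOD) — a column-integrated proxy
for particulate load — hourly at kilometer scale, but with large spatial
gaps wherever clouds (or smoke itself) defeat the retrieval. `pmwave`
implements a two-stage pipeline that turns these ingredients into hourly,
gap-free PM2.5 surfaces on a fine planar modeling grid:

1. **Gap filling.** For every hour, a random forest learns the observed
   satellite retrievals from a coarse background-model AOD (a reanalysis
   product regridded to the modeling resolution) and ten meteorological
   fields, then predicts the masked cells. Observed retrievals are never
   altered.
2. **Concentration modeling.** A single pooled random forest predicts
   ground PM2.5 from the gap-filled AOD and meteorology — after each
   gridded predictor has been decomposed into additive multiresolution
   components with an orthogonal Daubechies wavelet, so the model can weigh
   the smooth trend of a field separately from its fine-scale fluctuations.

The package also provides the grid machinery around the two stages
(nearest-cell assignment, hourly averaging, bilinear regridding,
inverse-distance-weighted downscaling, merging of reference-grade and
low-cost monitor records), SMOTE augmentation of scarce high-concentration
training rows, and three evaluation modes: out-of-bag (OOB) metrics, random
10-fold cross-validation, and leave-monitors-out spatial cross-validation.

## Wavelet multiresolution analysis

Every gridded predictor is flattened row-major into a one-dimensional
signal of `n_rows * n_cols` samples and decomposed with the Mallat pyramid:
at each level the running approximation is correlated with the lowpass /
highpass pair of a Daubechies filter (after boundary extension) and
downsampled by two. Reconstructing each band separately (all other bands
zeroed) yields the additive components

\[ S = l_J + h_1 + h_2 + \dots + h_J , \]

where `l_J` is the smooth approximation at scale `J` and `h_j` the detail
component at scale `j`. By linearity of the exact inverse transform the
identity holds to floating-point precision; the test suite asserts a
relative error below 1e-8 across families, lengths, and both extension
modes.

Choices worth stating explicitly:

* **1-D decomposition of the flattened field.** The decomposition operates
  over the spatial scan, not as a 2-D tensor transform. For a full-state
  1 km grid of 493,561 cells and the length-10 db5 filter this gives a
  maximum level of `floor(log2(493561 / 9)) = 15`, which is the package's
  `max_decomposition_level()`; the working level defaults to `J = 5`, where
  the level-5 detail is smooth enough to summarize high-frequency structure
  without degenerating into noise.
* **Filters.** `daubechies_filters(p)` constructs the extremal-phase
  Daubechies pair (orders 1–10, `p = 1` is Haar) by spectral factorization
  of the binomial half-band polynomial, normalized to `sum(h) = sqrt(2)`,
  `sum(h^2) = 1`. The highpass is the quadrature mirror
  `g[k] = (-1)^k h[L-1-k]`; this one sign convention is used everywhere,
  and worked examples in the tests state their expected signs under it.
* **Extension modes.** `"symmetric"` (half-point reflection, the common
  toolbox default) and `"periodic"` (an orthogonal periodized transform).
  Both reconstruct exactly; the periodized mode additionally conserves
  energy (Parseval), which the suite asserts at 1e-8. The conventions
  match an established wavelet library's layout exactly; a frozen fixture
  cross-checks all MRA bands at 1e-6.
* **Features.** The default specification mirrors the final model of the
  methodology the package implements: all six level-5 components of AOD;
  only `l5` for longwave flux, u-wind, surface pressure, boundary-layer
  height and specific humidity; `h1`, `h3`, `l5` for upward shortwave
  flux; raw 2 m temperature, v-wind, downward shortwave flux and relative
  humidity; plus the two planar cell-center coordinates — 20 predictors.
  Specific humidity is decomposed (its `l5` enters the model) even though
  it is not in the raw list; upward shortwave radiation and upward
  shortwave flux are treated as one variable.

## Forests, SMOTE, and validation

Both stages use bagged regression trees (via `ranger`) with the
methodology's stated hyperparameters `n_trees = 500`, `m_try = 4`; fits are
seeded and single-threaded, so identical inputs give identical ensembles.
The gap-filling stage defaults to wider leaves (`min_leaf = 30`): its
targets are noisy retrievals, and wider leaves average retrieval noise out
of the predictions instead of reproducing it. The PM2.5 stage keeps the
regression default (`min_leaf = 5`).

Variable importance is permutation importance on OOB samples; pruning
(`prune_by_importance()`) drops features below 0.5% of total importance by
default and never drops the last feature.

High concentrations are rare in training data, so `smote()` synthesizes
minority rows: each synthetic row is `seed + u * (neighbor - seed)`,
`u ~ U(0, 1)`, applied jointly to predictors and target, with neighbors
drawn among the `k = 5` nearest minority rows in z-scored predictor space.
The minority threshold defaults to 35 ug/m3 (a standard regulatory daily
benchmark) and synthesis stops at a 20% minority fraction — the
methodology states neither value, so both are configurable and logged.
Two leakage guards are structural rather than optional: SMOTE runs inside
each cross-validation fold (training rows only, after the split), and
synthetic rows never enter any metric — OOB and CV statistics are computed
on real rows exclusively. Inside a fold, SMOTE is skipped silently when the
minority is already at target or has too few members to interpolate;
calling `smote()` directly with fewer minority rows than neighbors is an
error.

`kfold_cv()` partitions rows into near-equal folds; `spatial_kfold_cv()`
partitions *monitors*, so every test location is unseen during training —
the harder, map-relevant task. Pooled R2 (coefficient of determination,
not squared correlation) and RMSE are computed over the concatenation of
all test-fold predictions, matching the identity
`pooled RMSE^2 = weighted mean of per-fold MSEs` that the suite asserts.
Spatially clustered (buffered) cross-validation is deliberately out of
scope: with strongly non-uniform monitor networks its folds degenerate.

## The synthetic scene generator

No public archive accompanies the methodology, so the package ships a
generator whose statistical structure exercises every stage:

* **Meteorology.** Ten fields (2 m temperature, u/v-wind, boundary-layer
  height, downward and upward shortwave flux, longwave flux, specific
  humidity, surface pressure, relative humidity) as Gaussian-smoothed
  white noise (`met_smooth_sigma = 9` cells) with AR(1) evolution across
  hours (rho = 0.8), scaled to realistic units, with diurnal cycles in
  temperature, shortwave flux and boundary-layer height.
* **AOD.** A smooth regional component plus a relative-humidity link plus
  four drifting Gaussian plumes (amplitude 0.5–0.8, footprint 8–11% of the
  domain, drift ~1.8 cells/hour) with rise-and-fall temporal profiles.
* **Satellite observation.** The retrieval adds independent noise with
  per-cell SD `0.10 + 0.12 * AOD` — absolute error grows with aerosol
  loading — and loses blob-shaped regions to clouds (30% by default,
  quantile-thresholded smooth noise, so the realized fraction is nearly
  exact). The noise lives in the observation, not the truth: the
  gap-filler averages it out of masked-cell predictions, while models
  that consume the raw satellite field inherit it. This is what makes the
  low-frequency AOD component genuinely more informative than the raw
  field, qualitatively reproducing the methodology's central claim.
* **Background AOD.** The truth block-averaged to a 5-cell coarse grid,
  mildly distorted (3% multiplicative + 0.015 additive coarse-scale
  error), then bilinearly regridded — a reanalysis product seen through
  its native resolution. It correlates strongly with the truth yet differs
  in every cell.
* **PM2.5.** `pm25 = base + a * smooth_aod + b * (T - 288) + c *
  exp(-PBLH / 500) + eps`, where `smooth_aod` is the 2-D
  Gaussian-smoothed (sigma 10 cells) true AOD — the low-frequency driver —
  and `eps` is i.i.d. Gaussian. Defaults
  (`base = 4, a = 60, b = -0.5, c = 12` ug/m3) give realistic levels
  (hourly means near 20 ug/m3, roughly 10–20% of cell-hours above the
  35 ug/m3 minority threshold during plume events). The scene records
  `theoretical_r2 = Var(signal) / (Var(signal) + noise_sd^2)` — the ceiling
  any model evaluated against noisy observations can reach; with
  `target_r2` set, the noise SD is calibrated against the realized signal
  variance so the ceiling is exact.
* **Monitors.** A sparse reference network and a denser low-cost network
  at jittered cell centers; low-cost sites are generated already
  calibrated (site-level bias optional, default 0), since sensor
  calibration is outside the package's scope. Reference records take
  absolute precedence over co-located low-cost records when merging onto
  cells.

What the generator does **not** emulate: plume chemistry and transport
physics, real geodesy (coordinates are planar), instrument drift,
spatially correlated retrieval failure aligned with the plumes themselves,
and the strong clustering of real monitor networks. Passing tests on these
scenes therefore demonstrate the pipeline's statistical correctness and
its qualitative behavior, not performance on any real archive.

## Problem sizes and benchmark conditions

The package's standing experiments use two configurations:

* the **default scene** (`scene_config()`): 100 x 100 grid, 24 hours, 210
  monitors, 30% cloud gaps — gap-filling experiments run on slices of a
  few hours of this scene;
* the **benchmark scene** (`benchmark_scene_config()`): 64 x 64 grid, 8
  hours, 680 monitors (about 5,400 training rows), slightly smoother
  meteorology (synoptic scale 12 cells), and noise calibrated to a
  theoretical R2 of exactly 0.85. The denser network reflects the
  situation the methodology targets (a reference network augmented by
  thousands of low-cost sensors). On one CPU the full benchmark —
  simulation, per-hour gap filling, feature assembly, both 10-fold
  cross-validations at 500 trees — runs in a few minutes.

The wavelet-versus-raw ablation replicates the paired comparison over
several fold/forest seeds at a reduced ensemble size (200 trees, 5 folds);
the comparison is paired on identical data, so the reduced size affects
both arms equally and only the replicate affordability motivated it.

## Numerical and design notes

* Cells are indexed row-major from 0 with centers at half-offsets;
  nearest-cell ties resolve to the lexicographically smaller `(row, col)`.
  Points up to half a cell outside the extent are clamped.
* IDW downscaling defaults to `power = 2, k = 4`; a target center
  coinciding with a source returns the source value exactly. Both IDW and
  bilinear regridding are convex combinations of source values and can
  never invent new extrema; bilinear regridding is exact on affine fields.
* Edge regridding clamps to the outermost coarse stencil.
* Gridded IO uses a plain-text format (a one-line JSON header with grid
  metadata, then `row,col,value` records with shortest-round-trip
  doubles), so write-then-read is bitwise lossless and the files remain
  diffable and versionable. NetCDF/GeoTIFF decoding of real archives is
  out of scope.
* Trained forests are not serialized. The pipeline's `predict` stage
  re-fits the pooled model deterministically from the written training
  table and configured seeds — reproducibility by construction rather
  than by binary artifact.
* Hours with zero satellite retrievals are skipped by the gap-filling
  stage and logged; their surfaces are simply absent, mirroring the
  stated limitation of the hourly design.
* `m_try` is validated against the predictor count at fit time; a constant
  training target is fitted but flagged, and its OOB R2 is reported as
  undefined rather than invented.

## Known limitations

* The 1-D scan decomposition mixes cells that are distant in the
  second spatial dimension at coarse levels; `l5` is a stripe average, not
  an isotropic smooth. The pooled model compensates by combining `l5`
  with mid-scale detail bands, but a 2-D wavelet would represent isotropic
  structure more directly.
* Scene realizations vary: plume placement interacts with the cloud mask,
  so per-hour gap-fill recovery fluctuates by several R2 points around its
  mean; pooled metrics over hours are the stable quantity.
* SMOTE interpolates in predictor space without regard to spatial
  adjacency; synthetic rows can pair distant monitors with similar
  predictor profiles.
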