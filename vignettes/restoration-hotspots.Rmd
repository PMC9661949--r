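---
title: "Mapping restoration hotspots across savannah mosaic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping restoration hotspots across savannah mosaic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restoscape)
```

## The problem

Tropical savannah regions are not uniform: grassland, savannah and woodland
& forest (W&F) physiognomies interleave at kilometre scales, each adapted to
distinct soil and disturbance regimes. Restoring cleared pastureland
therefore starts with a question moist-forest prioritization never has to
ask — *restore to what?* — and only then asks *where is restoration most
worthwhile?* `restoscape` answers both on a raster landscape: a restoration
vegetation type for every pasture cell, and an equal-weight multi-criteria
score built from potential species richness, net total biomass gain and
native-vegetation connectivity, with projected surface-temperature rise
reported alongside as a separate risk layer.

This vignette documents the model choices, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and the
numerical decisions a careful user should know about.

## Spatial model

All layers share one `grid_spec`: an `n_rows x n_cols` lattice of square
cells (default 100 m) in a projected equal-area CRS, row 1 at the north
edge, all distances between cell centres. Geographic (longitude/latitude)
inputs are rejected rather than silently reprojected, because every distance
in the pipeline (proximity typing, thinning, kernels, windows) is Euclidean.
Rasters serialize to plain-text ESRI ASCII grids with a JSON sidecar for the
CRS and layer kind; integer layers round-trip exactly and continuous layers
to better than 1e-6.

## Restoration typing

Every cell that is pasture in the current map is a candidate restoration
site. Two rules assign its target class:

* **Historical rule.** If the cell was grassland, savannah or W&F in the
  historical map, that class is assigned (provenance `historical`). This
  always wins over proximity.
* **Proximity rule.** Otherwise the cell takes the class of the nearest
  reference cell — current native cells plus historically native cells,
  with the current class winning where the two disagree, on the view that
  present-day vegetation best reflects present-day conditions. The search is
  implemented with an exact Euclidean distance transform per class, so
  results are independent of cell visit order; squared distances are
  integers in cell units, making comparisons exact. Ties between classes at
  identical distance are broken by the fixed priority savannah > W&F >
  grassland (savannah being the regionally dominant native class), a
  deterministic documented choice. Cells with no reference within
  `max_search_radius` (default 50 km) are marked not-restorable rather than
  extrapolated.

## Species richness

The richness layer stacks per-species habitat suitability models.

* **Cleaning** (`clean_occurrences`): in-bounds check, coordinate-precision
  floor (1 m), exact duplicate removal — each filter counted in a log.
* **Thinning** (`thin_occurrences`): greedy one-record-per-radius (default
  10 km) in (y, x, insertion) order; deterministic and idempotent. At the
  package's desk scale (a 12 km synthetic landscape) the pipeline config
  uses the scale analogue of 300 m; the operation default stays 10 km,
  appropriate for continental data.
* **Minimum records** (`filter_min_records`): species with fewer than 5
  post-thinning records are excluded — too few points to constrain even the
  ridge-penalized learner.
* **Background** (`background_sample`): 10 000 points (2 000 at desk scale)
  drawn from an Epanechnikov kernel density `K(u) = 1 - u²` summed over all
  records of all species. Sampling the background from collection effort
  rather than uniformly means the model contrasts *where the species was
  found* against *where anyone looked*, cancelling shared access bias. The
  kernel bandwidth is not identifiable from first principles; the default is
  one fifth of the longer grid extent, echoed in logs.
* **Learner** (`fit_sdm`): a presence-background binomial model with
  standardized linear + quadratic features and a fixed ridge penalty (1.0 on
  the summed log-likelihood scale, fitted via `glmnet` with
  `lambda = penalty/n`), reported through the complementary log-log link so
  outputs lie in [0, 1]. This is a documented surrogate for a
  maximum-entropy fit with default features: quadratic features capture
  unimodal responses, the ridge penalty plays the role of regularization,
  and cloglog is the conventional output transform. Everything downstream
  (cross-validation, Boyce evaluation, filtering, stacking) is agnostic to
  the learner. Exact duplicate features are collapsed before fitting so a
  duplicated predictor cannot split the penalty.
* **Evaluation** (`boyce_index`): presences are held out in 5 contiguous
  folds of a seed-shuffled split. The continuous Boyce index is the Spearman
  correlation between the presence-to-expected ratio P/E and the window
  centre, over 101 overlapping windows of width 0.1. Suitability is first
  passed through the background empirical CDF; this makes the index
  *exactly* invariant under strictly monotone transforms of the suitability
  scale (a property only approximately true when windows are placed on the
  raw scale) and costs nothing, since the index is rank-based by
  construction. Windows with no background mass are dropped; constant
  suitability has no defined index and returns `NA`. A model's mean
  cross-validated CBI below 0.25 removes it (`filter_models`) — the
  threshold sits well above the CBI > 0 "better than random" line.
* **Stacking** (`stack_richness`): retained models are summed per
  vegetation type over the species-to-type lookup; woody savannah species
  (flagged `woody_cerrado_sl`) count under W&F as well as savannah, because
  dense woody savannah is mapped as forest in the landcover legend.
  Continuous stacking (summing occurrence probabilities) is the default;
  binary stacking at a user threshold is available but not used by the
  pipeline, since thresholding discards information before a rank-based
  scoring stage.

## Biomass

Plot inventories give per-type AGB moments and, where belowground biomass
was also measured, root:shoot ratios (`inventory_summary`,
`root_shoot_stats`; the s.d. is the n−1 sample estimate, undefined for
single-plot types). The default calibration of the synthetic inventory is:
AGB 5.3 ± 3.2 (grassland, n = 29), 24.3 ± 16.2 (savannah, n = 86) and
127.6 ± 68.9 Mg ha⁻¹ (W&F, n = 21); R:S 2.3 ± 2.2 (n = 14), 1.8 ± 0.7
(n = 21) and 0.3 ± 0.2 (n = 4). The inverted R:S gradient — grassland
plants hold over twice as much biomass below ground as above, forest trees
barely a third — is why total-biomass accounting, not AGB alone, matters in
these systems.

The per-cell estimate chain is:

1. `localized_restoration_agb`: mean AGB over the nearest ≥ 10 current
   native cells of the assigned type (ties at the final radius included),
   capped at 20 km with a flagged global-type-mean fallback. Localizing the
   reference captures regional productivity gradients that a single type
   mean would erase.
2. `adjust_to_inventory`: the cellwise distribution is quantile-mapped, per
   type, onto the empirical inventory distribution. The map is strictly
   rank-preserving (Spearman 1 with its input) and clips to the inventory
   range; it corrects the level and spread of remote-sensed stocks while
   leaving the spatial ordering untouched. Types with fewer than 5 plots
   skip adjustment with a warning.
3. `total_biomass`: `AGB x (1 + mean R:S)` of the assigned type — type-level
   mean ratios, not per-cell draws.
4. `net_gain`: subtract the planted-pasture total-biomass baseline, a
   config scalar defaulting to 14 Mg ha⁻¹ (7 Mg ha⁻¹ AGB x (1 + R:S 1.0)),
   overridable and replaceable by a raster. Gains may be negative.

Soil organic carbon is deliberately absent from every computation: field
observations of SOC change after restoration are too sparse to calibrate.

## Connectivity

`native_fraction` is the percentage of native cells in a square moving
window centred on each cell, computed with a summed-area table. The default
window is 1.21 km² — exactly 11 x 11 cells at 100 m. Requested areas
without an exact odd-square realization snap to the nearest odd side (0.21
km² realizes as 5 x 5 = 0.25 km²) and the realized area is recorded. Edge
cells use the truncated window with its actual cell count as denominator,
keeping percentages interpretable everywhere. Square windows are used
throughout; at these window sizes the difference from a disc is immaterial
next to the window-area sensitivity itself, which `window_sensitivity`
quantifies directly by recomputing downstream scores across areas
(0.21–9.61 km² by default) and reporting their Spearman correlation matrix.

## Hotspot scoring

Scores are computed independently per vegetation type over that type's
restorable cells — the statistical population being ranked:

1. **Shift**: metrics with non-positive values (net gain can be negative,
   connectivity zero) are shifted by `1 - min(x)` so the minimum is exactly
   1. Anchoring to a fixed minimum also canonicalizes location, so additive
   changes to an anchored metric cannot change scores.
2. **Box-Cox** (`boxcox_transform`): `(x^λ - 1)/λ` (log at λ = 0), λ per
   metric per type by maximizing the profile log-likelihood over [-5, 5]
   with Brent search (tolerance 1e-6; tests cross-check against a 0.001-step
   grid). The transform is strictly increasing, so cell ranking is
   untouched; its only job is to stop heavy tails from compressing the rest
   of the scale after min-max scaling.
3. **Scale** to [0, 1]; a constant metric maps to 0.5 with a warning.
4. **Combine** (`combine_metrics`): unweighted mean over the type's metrics
   — richness and connectivity for grassland, plus net gain for savannah and
   W&F — then a final min-max rescale. A cell missing any metric is nodata;
   weights are never renormalized around missing data.
5. **Classify**: strict thresholds at 0.5 / 0.7 / 0.8 (a score of exactly
   0.5 is below-threshold).
6. **Combine across types** (`combined_hotspot`): each restorable cell takes
   its assigned type's score (per-type scoring followed by cellwise
   selection, rather than a global rescale across types); block aggregation
   to 5.5 km over pasture cells produces the display map.

Grassland's exclusion of net gain is structural: the grassland score is
computed without the layer, and perturbing net gain leaves grassland scores
bit-identical. Climate risk is likewise excluded by interface — no scoring
function accepts it — because rising temperatures argue both against
restoring (failure risk) and for it (desertification buffer); the package
reports the layer and leaves the trade-off to the planner.

## Climate risk

`stmax_delta` averages each model's monthly maximum-surface-temperature
layers within an initial and an end period (defaults emulate 2006–2016 vs
2090–2100), differences the period means, and reports the across-model mean
change in °C with the standard error of the mean as uncertainty (nodata for
a single model — one model has no spread). "Absolute" change is read as the
signed change in °C (as opposed to relative change); a `monthly_abs` mode
averages the absolute month-wise climatology differences instead, for
sensitivity to the aggregation order, and bounds the default mode from
above.

## Predictors

Five climate predictors and five edaphic principal components drive the
SDMs:

* Priestley–Taylor potential evapotranspiration with α = 1.26,
  γ = 0.066 kPa °C⁻¹, λ = 2.45 MJ kg⁻¹, the Tetens form for the saturation
  vapour-pressure slope, zero ground heat flux, and W m⁻² net radiation
  converted at 0.0864 MJ m⁻² day⁻¹ per W m⁻². Whether "equilibrium"
  evapotranspiration means α = 1.0 or the standard 1.26 is a genuine
  ambiguity; α is a config parameter defaulting to 1.26, and the moisture
  index MI = P/PET simply rescales with 1/α, which the rank-based scoring
  absorbs.
* Annual MI, minimum monthly MI, and dry-season length (months with MI
  strictly < 1).
* bio6 (coldest monthly minimum) and days with maximum temperature strictly
  above 25 °C — from a daily series when supplied, otherwise from a smooth
  cosine interpolation of the monthly climatology, flagged `interpolated`
  in the result.
* Edaphic variables are mean-imputed per variable, standardized (constant
  variables dropped with a warning), and reduced by PCA to the smallest
  axis count whose cumulative explained variance exceeds 80% — five axes
  under the default generator calibration. Means, s.d.s and loadings
  serialize to JSON so the exact transform reapplies to new sites.

## Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code; every pipeline input can be
produced with known ground truth, and each generator returns a `truth`
record for recovery tests.

* **Landcover** — smoothed-Gaussian-noise fields thresholded at
  class-fraction quantiles: one field decides anthropic vs native, a second
  partitions native classes, a third ranks native cells for 1985→2018
  conversion (80% to pasture, 20% to agriculture by default). This yields
  mosaic patch structure with exact class fractions and patch scale
  ~`patch_scale` (default 800–1000 m). Default class fractions (10/31/16/
  27/11/5% for grassland/savannah/W&F/pasture/agriculture/other) and the
  25% conversion fraction describe a heavily but not completely converted
  savannah region.
* **Climate/edaphic surfaces** — seasonal cosine cycles over smooth spatial
  gradients; edaphic variables mix five orthogonalized latent fields with
  balanced loadings plus noise (σ = 0.1), so the PCA stage has a recoverable
  true dimension.
* **Occurrences** — presences sampled proportional to a logistic function
  of the species' true coefficients on the standardized predictors,
  multiplied by a bump-field collection bias around synthetic access points
  — the bias the cleaning/thinning/background machinery exists to counter.
* **Inventory** — gamma draws affinely moment-matched so sample moments
  equal the calibration targets exactly (`exact_moments = TRUE`), with
  positivity enforced by deterministic redraws; `synthetic_plot_inventory()`
  is the package's labelled synthetic stand-in for a field compilation.
* **Climate projections** — a baseline field plus seasonal cycle, a shared
  warming trend with exactly moment-matched model offsets, and white
  per-layer noise.

What the generators do *not* emulate: georeferencing error and taxonomic
noise in occurrence data, fire and edaphic process dynamics, realistic
landcover legends beyond the seven-code scheme, non-stationary climate
trends within a period, and spatial autocorrelation in model *errors*.
Passing tests therefore demonstrate that the machinery is correct and
recovers known structure under realistic-shaped inputs — not that any
particular real-world map would be reproduced.

## Problem sizes and determinism

The package's desk scale — the default `run_pipeline` configuration — is a
120 x 120 grid of 100 m cells with 24 species, 60 records each, 2 000
background points and 4 climate models over 2-year periods; a full run
takes well under a minute and the whole test suite a couple of minutes.
Tests that compare against exhaustive oracles use grids up to 50 x 50,
where brute force is still exact and fast.

All randomness flows from one seed: each stage derives its own seed by
hashing the stage name into the run seed (`derive_seed`), so stages can be
rerun in isolation and full reruns are byte-identical (verified via raster
checksums in the run report). Generators are pure functions of
(parameters, seed).

## Known limitations

* The three broad classes cannot express sub-physiognomies (campo rupestre,
  cerradão, gallery forest); a finer legend would need a finer typing rule.
* The proximity rule weights current and historical references equally
  except that current wins on the same cell; alternative weightings are
  plausible and would need their own justification.
* The pasture biomass baseline is a single scalar by default; where spatial
  pasture-productivity data exist, pass a raster.
* The surrogate SDM learner is pluggable but not a maximum-entropy
  implementation; absolute suitability values differ even though the
  rank-based evaluation and scoring pipeline behaves identically.
* Scores rank restorable cells within this landscape and scoring
  population; they are not comparable across runs with different extents.
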