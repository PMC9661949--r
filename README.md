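# restoscape

Restoration hotspot mapping for savannah mosaic landscapes.

Savannah-dominated regions are mosaics of grassland, savannah and woodland &
forest (W&F), each tied to local soil and disturbance conditions — so a
single restoration prescription cannot be applied across a whole region.
`restoscape` implements a landscape-scale prioritization pipeline for such
regions, aimed at conservation planners and landscape ecologists:

1. **Restoration vegetation typing** — every current pasture cell is a
   potential restoration site; its target vegetation class is the cell's
   historical native cover where known, otherwise the class of the nearest
   remaining (or historically known) native vegetation.
2. **Potential plant species richness** — presence-background species
   distribution models (penalized binomial learner with linear + quadratic
   features, cloglog output) fitted per species with 5-fold cross-validation,
   evaluated with the continuous Boyce index (CBI), discarded when mean
   CBI < 0.25, and summed per vegetation type into stacked richness
   surfaces. Background points are drawn from an Epanechnikov kernel density
   of all occurrence records so the background carries the same collection
   bias as the presences; records are spatially thinned (one per 10 km by
   default) and species with fewer than five records are dropped.
3. **Net total biomass gain** — localized per-type aboveground biomass (AGB)
   stocks from the nearest remaining native vegetation, rank-preserving
   quantile adjustment to a plot-inventory distribution, conversion to total
   biomass with per-type mean root:shoot ratios
   (`total = AGB x (1 + R:S)`), minus a planted-pasture baseline.
4. **Connectivity** — the percentage of native vegetation in a 1.21 km²
   (11 x 11 cells at 100 m) moving window around each cell, with a
   sensitivity analysis over window areas from 0.21 to 9.61 km².
5. **Hotspot scoring** — each metric is Box-Cox transformed
   (`y = (x^λ - 1)/λ`, λ by profile likelihood), min-max scaled to [0, 1],
   and combined as an equal-weight mean per vegetation type (net biomass is
   excluded for grassland, where pasture-to-grassland conversion changes
   stocks negligibly). Scores > 0.5 / > 0.7 / > 0.8 mark medium / high /
   very-high hotspots; a combined map assigns every restorable cell its
   type's score and aggregates to 5.5 km for display.
6. **Climate risk** — the change in decadal-mean maximum surface temperature
   between two periods, averaged across climate models, with the standard
   error of the mean as multi-model uncertainty. Deliberately kept out of
   the hotspot score and reported as a separate layer.

Every input the pipeline consumes can be generated synthetically with known
ground truth (`landscape_scenario()`, `generate_landcover_pair()`,
`generate_predictor_stack()`, `generate_occurrences()`, `generate_agb()`,
`generate_inventory()`, `generate_climate_projection()`), so the full
analysis is testable end-to-end without external downloads. Rasters are read
and written as plain-text ESRI ASCII grids (`read_raster()` /
`write_raster()`).

## Worked example

```r
library(restoscape)

out <- run_pipeline(default_config(seed = 1))
rep <- out$report

round(100 * unlist(rep$stages$assign_type$type_fractions), 1)
#>       grassland        savannah woodland_forest
#>            13.3            63.1            23.6

c(kept = rep$stages$sdm$n_species_kept,
  modelled = rep$stages$sdm$n_species_modelled)
#>     kept modelled
#>       24       24

round(rep$stages$biomass$mean_gain, 1)
#>       grassland        savannah woodland_forest
#>             3.4            53.4           150.0

round(c(delta = rep$stages$climate_risk$mean_delta,
        se = rep$stages$climate_risk$mean_se), 2)
#> delta    se
#>  4.00  0.25
```

On this 120 x 120-cell synthetic landscape (100 m cells), 63% of the
restorable pasture is assigned to savannah restoration; all 24 synthetic
species survive the CBI filter; mean net total biomass gains are about 53
and 150 Mg ha⁻¹ for savannah and W&F restoration (grassland gains are
near zero and are excluded from grassland scoring); and the projected
maximum-surface-temperature rise of 4.00 ± 0.25 °C matches the warming the
climate generator was configured with. `out$results` holds every
intermediate layer (`value_grid` objects) including the combined hotspot
map and its 5.5 km aggregation.

A YAML config drives the same pipeline from a file:
`run_pipeline(read_config("run.yaml"))`; setting `out_dir` writes all key
rasters, the inventory table and a JSON run report with parameters, seeds,
per-stage counts, Box-Cox lambdas and raster checksums.

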