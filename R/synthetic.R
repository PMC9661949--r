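# Synthetic landscape generators. Every input the pipeline consumes can be
# generated here as a pure function of (parameters, seed), with a ground
# truth record attached so downstream stages can be tested by parameter
# recovery rather than against downloaded data.

.gauss_blur_mat <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
  K / rowSums(K)
}

# Spatially autocorrelated standard-normal field: white noise smoothed by a
# separable Gaussian kernel (correlation length `scale_cells`), then
# re-standardized. Deterministic given the RNG state.
.smooth_field <- function(n_rows, n_cols, scale_cells) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (scale_cells > 0) {
    z <- .gauss_blur_mat(n_rows, scale_cells) %*% z %*%
      t(.gauss_blur_mat(n_cols, scale_cells))
  }
  (z - mean(z)) / stats::sd(z)
}

# Affinely rescale positive draws to exact sample moments, keeping all
# values strictly positive (deterministic redraws if the rescale would
# cross zero). Used where the study conditions fix a sample mean/sd.
.moment_matched_positive <- function(n, mean, sd, base_seed, max_tries = 200L) {
  if (n == 1L) return(mean)
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  for (k in seq_len(max_tries)) {
    set.seed((base_seed + k) %% 2147483647L)
    x <- stats::rgamma(n, shape = shape, scale = sd^2 / mean)
    z <- (x - mean(x)) / stats::sd(x)
    out <- mean + sd * z
    if (all(out > 0)) return(out)
  }
  stop("could not generate strictly positive moment-matched sample")
}

#' Define a synthetic landscape scenario
#'
#' Bundles the parameters of the categorical landcover generator: target
#' class fractions, spatial autocorrelation length of the vegetation
#' mosaic, and the share of native cells converted to pasture/agriculture
#' between the historical and current maps.
#'
#' @param seed Integer seed; every generated layer is a pure function of
#'   the scenario and this seed.
#' @param spec A [grid_spec()].
#' @param class_fractions Named target proportions over [LC_CODES] classes
#'   (must sum to 1 within 1e-9).
#' @param patch_scale Autocorrelation length of the mosaic in metres.
#' @param conversion_fraction Share of historical native cells converted
#'   to pasture/agriculture in the current map, in `[0, 1]`.
#' @param agriculture_share Share of converted cells that become
#'   agriculture rather than pasture.
#' @return An object of class `landscape_scenario`.
#' @export
landscape_scenario <- function(seed, spec,
                               class_fractions = c(grassland = 0.10,
                                                   savannah = 0.31,
                                                   woodland_forest = 0.16,
                                                   pasture = 0.27,
                                                   agriculture = 0.11,
                                                   other = 0.05),
                               patch_scale = 1000,
                               conversion_fraction = 0.25,
                               agriculture_share = 0.2) {
  stopifnot(inherits(spec, "grid_spec"))
  cf <- class_fractions[names(LC_CODES)]
  if (anyNA(cf))
    stop("configuration error: class_fractions must name all landcover classes")
  if (abs(sum(cf) - 1) > 1e-9)
    stop("configuration error: class_fractions must sum to 1")
  if (conversion_fraction < 0 || conversion_fraction > 1)
    stop("configuration error: conversion_fraction must lie in [0, 1]")
  structure(list(seed = as.integer(seed), spec = spec, class_fractions = cf,
                 patch_scale = patch_scale,
                 conversion_fraction = conversion_fraction,
                 agriculture_share = agriculture_share),
            class = "landscape_scenario")
}

#' Generate a co-registered historical/current landcover pair
#'
#' Builds the historical map from two independent spatially autocorrelated
#' fields (smoothed Gaussian noise, thresholded at class-fraction
#' quantiles): an anthropic-pressure field decides which cells are already
#' converted (pasture / agriculture / other), and a vegetation-gradient
#' field partitions the remaining cells among the three native classes —
#' so converted patches border all native classes rather than a single
#' one. The current map then converts the scenario's fraction of native
#' cells (those ranking highest on a third smooth conversion-pressure
#' field) to pasture or agriculture; the two maps differ only by that
#' native-to-converted change.
#'
#' @param scenario A [landscape_scenario()].
#' @return List with `lc1985`, `lc2018` ([landcover_grid()]s) and `truth`
#'   (realized class counts and conversion record).
#' @export
generate_landcover_pair <- function(scenario) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  spec <- scenario$spec
  set.seed(derive_seed(scenario$seed, "landcover"))
  sc_cells <- scenario$patch_scale / spec$cell_size
  f_veg <- .smooth_field(spec$n_rows, spec$n_cols, sc_cells)
  f_ant <- .smooth_field(spec$n_rows, spec$n_cols, sc_cells)
  cf <- scenario$class_fractions
  anthro <- c("pasture", "agriculture", "other")
  frac_ant <- sum(cf[anthro])
  codes <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  is_ant <- if (frac_ant > 0) f_ant >= stats::quantile(f_ant, 1 - frac_ant)
            else matrix(FALSE, spec$n_rows, spec$n_cols)
  if (frac_ant > 0 && any(is_ant)) {
    # split anthropic cells among pasture/agriculture/other by pressure
    av <- f_ant[is_ant]
    aq <- stats::quantile(av, probs = cumsum(cf[anthro] / frac_ant),
                          names = FALSE)
    codes[is_ant] <- LC_CODES[anthro][pmin(3L, findInterval(
      av, aq[-3], left.open = TRUE) + 1L)]
  }
  nat <- which(!is_ant)
  if (length(nat)) {
    cfn <- cf[VEG_TYPES] / sum(cf[VEG_TYPES])
    nv <- f_veg[nat]
    nq <- stats::quantile(nv, probs = cumsum(cfn)[-3], names = FALSE)
    codes[nat] <- LC_CODES[VEG_TYPES][findInterval(nv, nq) + 1L]
  }
  lc1985 <- landcover_grid(spec, codes)

  codes18 <- codes
  native <- codes %in% NATIVE_CODES
  n_conv <- round(scenario$conversion_fraction * sum(native))
  if (n_conv > 0) {
    pressure <- .smooth_field(spec$n_rows, spec$n_cols, sc_cells)
    idx <- which(native)
    ord <- idx[order(pressure[idx], decreasing = TRUE)]
    conv <- ord[seq_len(n_conv)]
    n_agri <- round(scenario$agriculture_share * n_conv)
    # highest-pressure converted cells become agriculture, the rest pasture
    codes18[conv] <- LC_CODES[["pasture"]]
    if (n_agri > 0) codes18[conv[seq_len(n_agri)]] <- LC_CODES[["agriculture"]]
  }
  lc2018 <- landcover_grid(spec, codes18)
  count_classes <- function(m)
    as.list(table(factor(m, levels = LC_CODES, labels = names(LC_CODES))))
  list(lc1985 = lc1985, lc2018 = lc2018,
       truth = list(seed = scenario$seed,
                    class_counts_1985 = count_classes(codes),
                    class_counts_2018 = count_classes(codes18),
                    n_converted = n_conv))
}

#' Generate the environmental predictor inputs
#'
#' Emulates gridded monthly climatologies (precipitation, minimum / mean /
#' maximum temperature, net radiation) as smooth seasonal cycles over
#' spatial gradients, plus a table of edaphic variables built from a small
#' number of latent spatial factors with additive noise — so that a
#' principal-component reduction of the edaphic set has a known true
#' dimension.
#'
#' @param spec A [grid_spec()].
#' @param seed Integer seed.
#' @param n_edaphic Number of edaphic variables (default 55).
#' @param n_factors True latent dimension of the edaphic set (default 5).
#' @param edaphic_noise_sd Noise s.d. added to each edaphic variable.
#' @param precip_base Mean annual-cycle precipitation level (mm/month).
#' @param tmean_base Mean annual temperature (deg C).
#' @return List with elements `precip`, `tmin`, `tmax`, `tmean`,
#'   `net_radiation` (each a list of 12 monthly [value_grid()]s),
#'   `edaphic` (list of `n_edaphic` grids) and `truth` (latent factors,
#'   loadings, noise level).
#' @export
generate_predictor_stack <- function(spec, seed, n_edaphic = 55L,
                                     n_factors = 5L,
                                     edaphic_noise_sd = 0.1,
                                     precip_base = 110,
                                     tmean_base = 23) {
  stopifnot(inherits(spec, "grid_spec"))
  set.seed(derive_seed(seed, "predictors"))
  sc <- 8  # correlation length in cells for climate surfaces
  fp <- .smooth_field(spec$n_rows, spec$n_cols, sc)
  ft <- .smooth_field(spec$n_rows, spec$n_cols, sc)
  fr <- .smooth_field(spec$n_rows, spec$n_cols, sc)
  # north-south gradient on the matrix rows (row 1 = north edge)
  lat <- matrix(seq(1, -1, length.out = spec$n_rows), spec$n_rows, spec$n_cols)
  months <- 1:12
  seasonal <- function(m, phase) cos(2 * pi * (m - phase) / 12)
  mk <- function(vals) value_grid(spec, vals)
  precip <- lapply(months, function(m)
    mk(pmax(precip_base * (1 + 0.85 * seasonal(m, 1)) * (1 + 0.30 * fp + 0.15 * lat), 0)))
  tmean <- lapply(months, function(m)
    mk(tmean_base + 2.5 * seasonal(m, 10) + 2.0 * ft + 1.5 * lat))
  tmin <- lapply(months, function(m)
    mk(tmean[[m]]$values - 7 - 1.0 * seasonal(m, 10)))
  tmax <- lapply(months, function(m)
    mk(tmean[[m]]$values + 7 + 1.0 * seasonal(m, 1)))
  net_radiation <- lapply(months, function(m)
    mk(pmax(140 + 25 * seasonal(m, 12) + 10 * fr, 0)))

  # latent factors: smooth fields, orthogonalized over cells and scaled to
  # unit variance; loading rows normalized so each factor contributes the
  # same total variance — the latent dimension is then recoverable by the
  # explained-variance rule
  fm <- vapply(seq_len(n_factors), function(i)
    as.vector(.smooth_field(spec$n_rows, spec$n_cols, sc)),
    numeric(spec$n_rows * spec$n_cols))
  fm <- scale(fm, center = TRUE, scale = FALSE)
  fm <- qr.Q(qr(fm))
  fm <- scale(fm, center = FALSE, scale = apply(fm, 2L, stats::sd))
  loadings <- matrix(stats::rnorm(n_factors * n_edaphic), n_factors, n_edaphic)
  loadings <- loadings / sqrt(rowSums(loadings^2))
  factors <- lapply(seq_len(n_factors), function(i)
    matrix(fm[, i], spec$n_rows, spec$n_cols))
  edaphic <- lapply(seq_len(n_edaphic), function(v) {
    x <- matrix(fm %*% loadings[, v], spec$n_rows, spec$n_cols)
    if (edaphic_noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = edaphic_noise_sd),
                      nrow(x), ncol(x))
    mk(x)
  })
  names(edaphic) <- sprintf("edaphic_%02d", seq_len(n_edaphic))
  list(precip = precip, tmin = tmin, tmax = tmax, tmean = tmean,
       net_radiation = net_radiation, edaphic = edaphic,
       truth = list(seed = seed, n_factors = n_factors,
                    edaphic_noise_sd = edaphic_noise_sd,
                    loadings = loadings,
                    factors = lapply(factors, identity)))
}

#' Define a species niche for the occurrence generator
#'
#' @param species_id Species identifier.
#' @param coefficients Named numeric vector of true responses on the
#'   (standardized) predictor surfaces; names must match predictor names.
#' @param prevalence Intercept of the logistic suitability (controls how
#'   widespread the species is).
#' @param veg_types Character subset of [VEG_TYPES] the species occupies
#'   (at least one).
#' @param n_records Number of occurrence records to draw (>= 0).
#' @param bias_strength Strength in `[0, 1]` of the collection-bias field
#'   applied when sampling records (0 = unbiased).
#' @param woody_cerrado_sl Logical; marks a woody savannah species that is
#'   also classified under woodland & forest when vegetation types are
#'   assigned.
#' @return An object of class `niche_spec`.
#' @export
niche_spec <- function(species_id, coefficients, prevalence = 0,
                       veg_types = "savannah", n_records = 30L,
                       bias_strength = 0.5, woody_cerrado_sl = FALSE) {
  if (!length(veg_types) || !all(veg_types %in% VEG_TYPES))
    stop("veg_types must be a non-empty subset of VEG_TYPES")
  if (n_records < 0) stop("n_records must be >= 0")
  structure(list(species_id = as.character(species_id),
                 coefficients = coefficients, prevalence = prevalence,
                 veg_types = veg_types, n_records = as.integer(n_records),
                 bias_strength = bias_strength,
                 woody_cerrado_sl = isTRUE(woody_cerrado_sl)),
            class = "niche_spec")
}

# standardize a predictor surface over its finite cells
.std_surface <- function(grid) {
  v <- grid$values
  mu <- mean(v, na.rm = TRUE)
  sg <- stats::sd(v, na.rm = TRUE)
  if (!is.finite(sg) || sg == 0) sg <- 1
  (v - mu) / sg
}

#' True suitability surface implied by a niche
#'
#' Logistic suitability from the niche's true coefficients on the
#' standardized predictor surfaces; the ground truth that recovery tests
#' compare fitted models against.
#'
#' @param niche A [niche_spec()].
#' @param predictors Named list of aligned [value_grid()]s.
#' @return A [value_grid()] of true suitability in `[0, 1]`.
#' @export
niche_suitability <- function(niche, predictors) {
  stopifnot(inherits(niche, "niche_spec"), length(predictors) >= 1)
  spec <- predictors[[1]]$spec
  eta <- matrix(niche$prevalence, spec$n_rows, spec$n_cols)
  for (nm in names(niche$coefficients)) {
    if (!nm %in% names(predictors))
      stop(sprintf("niche coefficient '%s' has no matching predictor", nm))
    eta <- eta + niche$coefficients[[nm]] * .std_surface(predictors[[nm]])
  }
  value_grid(spec, stats::plogis(eta))
}

#' Generate species occurrence records from known niches
#'
#' Draws per-species presence records with probability proportional to the
#' niche's true logistic suitability, multiplied by a shared collection-bias
#' surface (an Epanechnikov-like bump field around synthetic access points,
#' emulating roads/towns bias in herbarium data). Records are placed at a
#' uniform position inside the sampled cell.
#'
#' @param niches List of [niche_spec()]s (non-empty).
#' @param predictors Named list of aligned predictor [value_grid()]s.
#' @param seed Integer seed.
#' @param n_bias_centres Number of synthetic access points for the bias
#'   field.
#' @return List with `occurrences` (data.frame `species_id`, `x`, `y`) and
#'   `truth` (the niches and the bias surface checksum).
#' @export
generate_occurrences <- function(niches, predictors, seed,
                                 n_bias_centres = 5L) {
  if (!length(niches)) stop("configuration error: empty niche list")
  spec <- predictors[[1]]$spec
  set.seed(derive_seed(seed, "occurrences"))
  nr <- spec$n_rows
  nc <- spec$n_cols
  # bias field: bumps of radius ~ a third of the grid around access points
  ctr <- cbind(stats::runif(n_bias_centres, 1, nr),
               stats::runif(n_bias_centres, 1, nc))
  h <- max(nr, nc) / 3
  rows <- row(matrix(0, nr, nc))
  cols <- col(matrix(0, nr, nc))
  bias <- matrix(0, nr, nc)
  for (k in seq_len(n_bias_centres)) {
    u2 <- ((rows - ctr[k, 1])^2 + (cols - ctr[k, 2])^2) / h^2
    bias <- bias + pmax(0, 1 - u2)
  }
  bias <- bias / max(bias)
  out <- vector("list", length(niches))
  for (i in seq_along(niches)) {
    ni <- niches[[i]]
    if (ni$n_records == 0L) next
    suit <- niche_suitability(ni, predictors)$values
    w <- suit * ((1 - ni$bias_strength) + ni$bias_strength * bias)
    if (all(w <= 0)) stop("configuration error: zero sampling weight everywhere")
    cells <- sample.int(nr * nc, ni$n_records, replace = TRUE, prob = as.vector(w))
    rr <- ((cells - 1L) %% nr) + 1L
    cc <- ((cells - 1L) %/% nr) + 1L
    ctr_xy <- cell_centre(spec, rr, cc)
    jx <- stats::runif(ni$n_records, -0.5, 0.5) * spec$cell_size
    jy <- stats::runif(ni$n_records, -0.5, 0.5) * spec$cell_size
    out[[i]] <- data.frame(species_id = ni$species_id,
                           x = ctr_xy[, 1] + jx, y = ctr_xy[, 2] + jy,
                           stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(occ))
    occ <- data.frame(species_id = character(), x = numeric(), y = numeric())
  rownames(occ) <- NULL
  list(occurrences = occ,
       truth = list(seed = seed,
                    species = vapply(niches, `[[`, "", "species_id"),
                    n_records = vapply(niches, `[[`, 0L, "n_records")))
}

#' Generate an aboveground-biomass surface stratified by landcover
#'
#' Per-type lognormal biomass surfaces over a shared smooth spatial field,
#' normalized within each landcover stratum so the stratified cell mean
#' equals the target exactly; `sd = 0` collapses a stratum to its mean.
#' Nodata landcover yields nodata biomass.
#'
#' @param landcover A [landcover_grid()].
#' @param type_means,type_sds Named vectors (Mg/ha) over landcover class
#'   names; classes absent from `type_means` get nodata.
#' @param noise_scale Autocorrelation length of the biomass field (m).
#' @param seed Integer seed.
#' @return List with `agb` ([value_grid()]) and `truth` (targets).
#' @export
generate_agb <- function(landcover,
                         type_means = c(grassland = 5.3, savannah = 24.3,
                                        woodland_forest = 127.6,
                                        pasture = 7, agriculture = 5,
                                        other = 2),
                         type_sds = c(grassland = 3.2, savannah = 16.2,
                                      woodland_forest = 68.9,
                                      pasture = 2, agriculture = 2,
                                      other = 1),
                         noise_scale = 800, seed = 1L) {
  stopifnot(inherits(landcover, "landcover_grid"))
  spec <- landcover$spec
  set.seed(derive_seed(seed, "agb"))
  f <- .smooth_field(spec$n_rows, spec$n_cols, noise_scale / spec$cell_size)
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  for (cls in names(type_means)) {
    code <- LC_CODES[[cls]]
    sel <- which(!is.na(landcover$codes) & landcover$codes == code)
    if (!length(sel)) next
    m <- type_means[[cls]]
    s <- if (cls %in% names(type_sds)) type_sds[[cls]] else 0
    if (s <= 0 || length(sel) < 2L) {
      out[sel] <- m
    } else {
      z <- f[sel]
      z <- (z - mean(z)) / stats::sd(z)
      cv <- s / m
      v <- exp(cv * z)
      out[sel] <- m * v / mean(v)  # exact stratified mean
    }
  }
  list(agb = value_grid(spec, out),
       truth = list(seed = seed, type_means = as.list(type_means),
                    type_sds = as.list(type_sds)))
}

#' Generate a plot-inventory table
#'
#' Emulates a compilation of vegetation plot inventories: per-type
#' aboveground biomass for every plot and belowground biomass for a paired
#' subset, from which root:shoot ratios can be derived. With
#' `exact_moments = TRUE` (default) the per-type sample mean and s.d. of
#' AGB, and of the paired-row R:S ratios, equal the requested targets
#' exactly (positive draws affinely moment-matched), so summary statistics
#' recomputed from the rows reproduce the targets.
#'
#' @param n Named integer vector of plots per vegetation type.
#' @param agb_means,agb_sds Per-type AGB targets (Mg/ha).
#' @param rs_means,rs_sds Per-type root:shoot ratio targets.
#' @param n_pairs Named integer vector of plots per type with both AGB and
#'   BGB; overrides `paired_fraction`.
#' @param paired_fraction Fraction of plots with BGB when `n_pairs` is
#'   `NULL`.
#' @param seed Integer seed.
#' @param exact_moments Match sample moments exactly (default `TRUE`).
#' @return List with `inventory` (data.frame `site_id`,
#'   `vegetation_type`, `agb_mg_ha`, `bgb_mg_ha`) and `truth`.
#' @export
generate_inventory <- function(n = c(grassland = 29L, savannah = 86L,
                                     woodland_forest = 21L),
                               agb_means = c(grassland = 5.3, savannah = 24.3,
                                             woodland_forest = 127.6),
                               agb_sds = c(grassland = 3.2, savannah = 16.2,
                                           woodland_forest = 68.9),
                               rs_means = c(grassland = 2.3, savannah = 1.8,
                                            woodland_forest = 0.3),
                               rs_sds = c(grassland = 2.2, savannah = 0.7,
                                          woodland_forest = 0.2),
                               n_pairs = c(grassland = 14L, savannah = 21L,
                                           woodland_forest = 4L),
                               paired_fraction = NULL, seed = 1L,
                               exact_moments = TRUE) {
  base <- derive_seed(seed, "inventory")
  rows <- list()
  for (t in names(n)) {
    nt <- as.integer(n[[t]])
    if (nt < 1L) next
    np <- if (!is.null(paired_fraction)) as.integer(round(paired_fraction * nt))
          else as.integer(n_pairs[[t]])
    np <- min(np, nt)
    if (exact_moments) {
      agb <- .moment_matched_positive(nt, agb_means[[t]], agb_sds[[t]],
                                      base + match(t, names(n)) * 1000L)
    } else {
      set.seed((base + match(t, names(n)) * 1000L) %% 2147483647L)
      agb <- pmax(0.01, stats::rnorm(nt, agb_means[[t]], agb_sds[[t]]))
    }
    bgb <- rep(NA_real_, nt)
    if (np >= 1L) {
      if (exact_moments) {
        rs <- .moment_matched_positive(np, rs_means[[t]], rs_sds[[t]],
                                       base + match(t, names(n)) * 1000L + 500L)
      } else {
        rs <- pmax(0.01, stats::rnorm(np, rs_means[[t]], rs_sds[[t]]))
      }
      bgb[seq_len(np)] <- rs * agb[seq_len(np)]
    }
    rows[[t]] <- data.frame(
      site_id = sprintf("%s_%03d", substr(t, 1, 2), seq_len(nt)),
      vegetation_type = t, agb_mg_ha = agb, bgb_mg_ha = bgb,
      stringsAsFactors = FALSE)
  }
  inv <- do.call(rbind, rows)
  rownames(inv) <- NULL
  list(inventory = inv,
       truth = list(seed = seed, n = as.list(n),
                    agb_means = as.list(agb_means), agb_sds = as.list(agb_sds),
                    rs_means = as.list(rs_means), rs_sds = as.list(rs_sds),
                    n_pairs = as.list(if (is.null(paired_fraction)) n_pairs
                                      else round(paired_fraction * n))))
}

#' Synthetic plot-inventory compilation
#'
#' A convenience wrapper around [generate_inventory()] with its default
#' calibration: a fully synthetic stand-in for a field plot-inventory
#' compilation, with per-type plot counts (grassland 29, savannah 86,
#' woodland & forest 21), AGB moments (5.3 +/- 3.2, 24.3 +/- 16.2,
#' 127.6 +/- 68.9 Mg/ha) and paired root:shoot moments (2.3 +/- 2.2 with
#' n = 14, 1.8 +/- 0.7 with n = 21, 0.3 +/- 0.2 with n = 4) matched
#' exactly by construction.
#'
#' @param seed Integer seed.
#' @return A data.frame inventory (see [generate_inventory()]).
#' @export
synthetic_plot_inventory <- function(seed = 1L) {
  generate_inventory(seed = seed)$inventory
}

#' Generate multi-model decadal maximum-surface-temperature projections
#'
#' Emulates downscaled climate-model output: for each model, monthly
#' maximum-surface-temperature layers over an initial and an end period.
#' End-period layers exceed the initial baseline by a shared warming trend
#' plus a model-specific offset; with `exact_offsets = TRUE` the offsets'
#' sample mean and s.d. across models equal `warming_mean`/`warming_sd`
#' exactly.
#'
#' @param spec A [grid_spec()].
#' @param n_models Number of climate models (>= 1).
#' @param baseline Mean baseline maximum surface temperature (deg C).
#' @param warming_mean Mean warming between the two periods (deg C).
#' @param warming_sd Inter-model s.d. of the warming (deg C).
#' @param n_years Years per period (each contributes 12 monthly layers).
#' @param noise_sd Per-layer white-noise s.d. (deg C).
#' @param seed Integer seed.
#' @param exact_offsets Match offset sample moments exactly when
#'   `n_models >= 2`.
#' @return List with `models` (per model: `initial` and `end` lists of
#'   monthly [value_grid()]s) and `truth` (the per-model offsets).
#' @export
generate_climate_projection <- function(spec, n_models = 4L, baseline = 33,
                                        warming_mean = 4, warming_sd = 0.5,
                                        n_years = 2L, noise_sd = 0.1,
                                        seed = 1L, exact_offsets = TRUE) {
  stopifnot(inherits(spec, "grid_spec"), n_models >= 1L, n_years >= 1L)
  set.seed(derive_seed(seed, "climate"))
  base_field <- baseline + 1.5 * .smooth_field(spec$n_rows, spec$n_cols, 6)
  season <- 4 * cos(2 * pi * ((1:12) - 1) / 12)
  if (n_models == 1L || warming_sd <= 0) {
    offsets <- rep(warming_mean, n_models)
  } else {
    z <- stats::rnorm(n_models)
    if (exact_offsets) z <- (z - mean(z)) / stats::sd(z)
    offsets <- warming_mean + warming_sd * z
  }
  layer <- function(mon, shift) {
    v <- base_field + season[mon] + shift
    if (noise_sd > 0)
      v <- v + matrix(stats::rnorm(length(v), sd = noise_sd), nrow(v), ncol(v))
    value_grid(spec, v)
  }
  models <- lapply(seq_len(n_models), function(m) {
    list(initial = lapply(rep(1:12, n_years), layer, shift = 0),
         end = lapply(rep(1:12, n_years), layer, shift = offsets[m]))
  })
  names(models) <- sprintf("model_%d", seq_len(n_models))
  list(models = models,
       truth = list(seed = seed, offsets = offsets,
                    warming_mean = warming_mean, warming_sd = warming_sd))
}

#' Write a generator's ground-truth record to JSON
#'
#' @param generated A list returned by any generator (must contain
#'   `truth`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(generated, path) {
  if (is.null(generated$truth)) stop("object carries no ground-truth record")
  tr <- generated$truth
  tr$factors <- NULL  # drop large raster payloads from the sidecar
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
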