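# End-to-end orchestration: simulate -> assign-type -> predictors -> sdm ->
# biomass -> connectivity -> hotspot -> climate-risk, from a single config,
# with a run report capturing parameters, counts and output checksums.

#' Default pipeline configuration
#'
#' Returns the full configuration list consumed by [run_pipeline()], at
#' the package's desk scale: a 120 x 120 grid of 100 m cells (12 x 12 km)
#' with 24 synthetic species. All distances are in metres. Any element
#' can be overridden via `...` (top-level names replace whole
#' sub-lists' elements by name).
#'
#' @param seed Global seed; per-stage seeds are derived from it with
#'   [derive_seed()].
#' @param ... Named overrides, e.g. `grid = list(n_rows = 60)`.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    grid = list(n_rows = 120L, n_cols = 120L, cell_size = 100,
                origin_x = 0, origin_y = 0, crs_id = "ESRI:102033"),
    scenario = list(class_fractions = c(grassland = 0.10, savannah = 0.31,
                                        woodland_forest = 0.16,
                                        pasture = 0.27, agriculture = 0.11,
                                        other = 0.05),
                    patch_scale = 800, conversion_fraction = 0.25,
                    agriculture_share = 0.2),
    predictors = list(n_edaphic = 55L, n_factors = 5L,
                      edaphic_noise_sd = 0.1, alpha = 1.26),
    species = list(n_species = 24L, n_records = 60L, niche_strength = 3,
                   prevalence = -1, bias_strength = 0.5,
                   woody_every = 4L),
    sdm = list(thin_radius = 300, min_records = 5L, background_n = 2000L,
               bandwidth = NULL, folds = 5L, penalty = 1.0, cbi_min = 0.25,
               stack_mode = "continuous"),
    typing = list(max_search_radius = 50000),
    biomass = list(min_refs = 10L, max_radius = 20000, pasture_total = 14),
    connectivity = list(window_km2 = 1.21),
    hotspot = list(block_size = 5500),
    climate = list(n_models = 4L, baseline = 33, warming_mean = 4,
                   warming_sd = 0.5, n_years = 2L, noise_sd = 0.1),
    stages = list(climate_risk = TRUE),
    out_dir = NULL
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(dots[[nm]])) cfg[[nm]][[k]] <- dots[[nm]][[k]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads named overrides from a YAML file and merges them over
#' [default_config()].
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("input error: cannot read '%s'", path))
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario$class_fractions))
    y$scenario$class_fractions <- unlist(y$scenario$class_fractions)
  do.call(default_config,
          c(list(seed = if (is.null(y$seed)) 1L else y$seed),
            y[setdiff(names(y), "seed")]))
}

#' Build the default synthetic species set
#'
#' One niche per species: vegetation types cycled over grassland /
#' savannah / woodland & forest, a strong response on one predictor
#' (cycled over the available predictor surfaces), and every
#' `woody_every`-th savannah species flagged as woody (gaining the
#' woodland & forest type). Also returns the matching vegetation-type
#' lookup table.
#'
#' @param predictor_names Names of the predictor surfaces.
#' @param cfg_species The `species` block of [default_config()].
#' @param seed Integer seed (used for sign flips of the niche direction).
#' @return List with `niches` (list of [niche_spec()]) and `lookup`
#'   (data.frame).
#' @export
default_niches <- function(predictor_names, cfg_species, seed = 1L) {
  set.seed(derive_seed(seed, "niches"))
  n <- cfg_species$n_species
  niches <- vector("list", n)
  lookup <- data.frame(species_id = character(n),
                       vegetation_types = character(n),
                       woody_cerrado_sl = logical(n),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sp <- sprintf("sp%03d", i)
    tp <- VEG_TYPES[((i - 1L) %% 3L) + 1L]
    pred <- predictor_names[((i - 1L) %% length(predictor_names)) + 1L]
    woody <- tp == "savannah" &&
      (i %% max(1L, cfg_species$woody_every)) == 0L
    coef <- stats::setNames(cfg_species$niche_strength * sample(c(-1, 1), 1),
                            pred)
    niches[[i]] <- niche_spec(sp, coef, prevalence = cfg_species$prevalence,
                              veg_types = tp,
                              n_records = cfg_species$n_records,
                              bias_strength = cfg_species$bias_strength,
                              woody_cerrado_sl = woody)
    lookup$species_id[i] <- sp
    lookup$vegetation_types[i] <- tp
    lookup$woody_cerrado_sl[i] <- woody
  }
  list(niches = niches, lookup = lookup)
}

#' Run the full restoration-hotspot pipeline
#'
#' Executes the stages in dependency order on a synthetic landscape:
#' input simulation, restoration-type assignment, predictor derivation,
#' species distribution modelling and richness stacking, net biomass
#' gain, connectivity, hotspot scoring/combination, and (optionally) the
#' separate climate-risk layer. All randomness flows from per-stage seeds
#' derived from `config$seed`, so rerunning an identical config
#' reproduces identical outputs (the report records raster checksums to
#' verify this). If `config$out_dir` is set, key rasters and tables are
#' written there.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()], or a YAML path.
#' @return List with `results` (grids, models, tables) and `report`
#'   (per-stage parameters, counts, lambdas, checksums).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  seed <- config$seed
  report <- list(seed = seed, stages = list())
  t0 <- Sys.time()

  spec <- do.call(grid_spec, config$grid)

  # --- simulate -------------------------------------------------------
  .log_msg("simulate", "seed %d, grid %dx%d", seed, spec$n_rows, spec$n_cols)
  scen <- landscape_scenario(
    seed = seed, spec = spec,
    class_fractions = config$scenario$class_fractions,
    patch_scale = config$scenario$patch_scale,
    conversion_fraction = config$scenario$conversion_fraction,
    agriculture_share = config$scenario$agriculture_share)
  lc <- generate_landcover_pair(scen)
  raw <- generate_predictor_stack(
    spec, seed, n_edaphic = config$predictors$n_edaphic,
    n_factors = config$predictors$n_factors,
    edaphic_noise_sd = config$predictors$edaphic_noise_sd)
  agb_gen <- generate_agb(lc$lc2018, seed = seed)
  inv <- generate_inventory(seed = seed)
  report$stages$simulate <- list(
    class_counts_2018 = lc$truth$class_counts_2018,
    n_converted = lc$truth$n_converted)

  # --- predictors -----------------------------------------------------
  derived <- compute_predictor_stack(raw, alpha = config$predictors$alpha)
  preds <- derived$predictors
  report$stages$predictors <- list(
    n_axes = derived$pca$n_axes,
    cum_explained = sum(derived$pca$explained[seq_len(derived$pca$n_axes)]),
    predictor_names = names(preds))

  # --- occurrences / sdm ----------------------------------------------
  sp_set <- default_niches(names(preds), config$species, seed)
  occ_gen <- generate_occurrences(sp_set$niches, preds, seed)
  occ <- clean_occurrences(occ_gen$occurrences, spec)
  occ_thin <- thin_occurrences(occ, radius = config$sdm$thin_radius)
  occ_kept <- filter_min_records(occ_thin, min_n = config$sdm$min_records)
  bg <- background_sample(occ, spec, n = config$sdm$background_n,
                          bandwidth = config$sdm$bandwidth, seed = seed)
  species <- unique(occ_kept$species_id)
  models <- lapply(species, function(sp) {
    fit_sdm(occ_kept[occ_kept$species_id == sp, c("x", "y")], bg$points,
            preds, species_id = sp, folds = config$sdm$folds,
            seed = seed, penalty = config$sdm$penalty)
  })
  kept_models <- filter_models(models, cbi_min = config$sdm$cbi_min)
  type_sets <- assign_vegetation_types(
    vapply(kept_models, `[[`, "", "species_id"), sp_set$lookup)
  richness <- stack_richness(kept_models, type_sets,
                             mode = config$sdm$stack_mode)
  report$stages$sdm <- list(
    n_records_raw = nrow(occ_gen$occurrences),
    n_records_clean = nrow(occ), n_records_thinned = nrow(occ_thin),
    n_species_modelled = length(species),
    n_species_kept = length(kept_models),
    cbi = stats::setNames(vapply(models, `[[`, 0, "cbi_mean"), species))

  # --- restoration typing ---------------------------------------------
  rtype <- assign_restoration_type(
    lc$lc1985, lc$lc2018,
    max_search_radius = config$typing$max_search_radius)
  fr <- type_fractions(rtype)
  report$stages$assign_type <- list(
    type_fractions = as.list(fr),
    n_not_restorable = sum(rtype$codes == RT_NOT_RESTORABLE, na.rm = TRUE))

  # --- biomass --------------------------------------------------------
  inv_sum <- inventory_summary(inv$inventory)
  rs <- root_shoot_stats(inv$inventory)
  local_agb <- localized_restoration_agb(
    agb_gen$agb, lc$lc2018, rtype,
    min_refs = config$biomass$min_refs,
    max_radius = config$biomass$max_radius)
  adj_agb <- adjust_to_inventory(local_agb, rtype, inv$inventory)
  total <- total_biomass(adj_agb, rtype, rs)
  gain <- net_gain(total, config$biomass$pasture_total)
  report$stages$biomass <- list(
    inventory = inv_sum, root_shoot = rs,
    mean_gain = stats::setNames(
      vapply(VEG_TYPES, function(tp)
        mean(gain$values[!is.na(rtype$codes) &
                           rtype$codes == LC_CODES[[tp]]], na.rm = TRUE), 0),
      VEG_TYPES))

  # --- connectivity ---------------------------------------------------
  win <- window_spec(config$connectivity$window_km2, spec$cell_size)
  conn <- native_fraction(lc$lc2018, win)
  report$stages$connectivity <- list(
    requested_km2 = win$area_km2, realized_km2 = win$realized_km2,
    side = win$side)

  # --- hotspot --------------------------------------------------------
  hs <- score_hotspots(richness, gain, conn, rtype)
  comb <- combined_hotspot(hs, rtype, lc$lc2018,
                           block_size = config$hotspot$block_size)
  class_counts <- table(factor(
    comb$classes$values[!is.na(comb$classes$values)], levels = 0:3,
    labels = c("below", "medium", "high", "very_high")))
  report$stages$hotspot <- list(
    lambdas = hs$lambdas, shifts = hs$shifts,
    class_counts = as.list(class_counts))

  # --- climate risk (separate layer, never a hotspot input) ------------
  risk <- NULL
  if (isTRUE(config$stages$climate_risk)) {
    proj <- generate_climate_projection(
      spec, n_models = config$climate$n_models,
      baseline = config$climate$baseline,
      warming_mean = config$climate$warming_mean,
      warming_sd = config$climate$warming_sd,
      n_years = config$climate$n_years,
      noise_sd = config$climate$noise_sd, seed = seed)
    risk <- stmax_delta(proj$models)
    report$stages$climate_risk <- list(
      n_models = risk$n_models,
      mean_delta = mean(risk$delta_stmax$values),
      mean_se = mean(risk$uncertainty$values))
  }

  results <- list(spec = spec, lc1985 = lc$lc1985, lc2018 = lc$lc2018,
                  predictors = preds, pca = derived$pca,
                  occurrences = occ_kept, background = bg$points,
                  models = models, kept_models = kept_models,
                  richness = richness, rtype = rtype,
                  inventory = inv$inventory, inventory_summary = inv_sum,
                  root_shoot = rs, agb = agb_gen$agb, adjusted_agb = adj_agb,
                  total_biomass = total, net_gain = gain,
                  connectivity = conn, hotspots = hs, combined = comb,
                  climate_risk = risk)
  report$checksums <- list(
    combined_fine = .grid_checksum(comb$fine),
    connectivity = .grid_checksum(conn),
    net_gain = .grid_checksum(gain))
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(g, nm) write_raster(g, file.path(config$out_dir,
                                                    paste0(nm, ".asc")))
    wr(lc$lc1985, "lc1985")
    wr(lc$lc2018, "lc2018")
    wr(conn, "connectivity")
    wr(gain, "net_gain")
    wr(comb$fine, "hotspot_combined")
    if (!is.null(comb$coarse)) wr(comb$coarse, "hotspot_combined_5p5km")
    if (!is.null(risk)) {
      wr(risk$delta_stmax, "stmax_delta")
      wr(risk$uncertainty, "stmax_uncertainty")
    }
    utils::write.csv(inv$inventory,
                     file.path(config$out_dir, "inventory.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(results = results, report = report)
}
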