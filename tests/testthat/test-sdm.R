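test_that("thinning keeps one record inside the radius and two outside", {
  tb <- data.frame(species_id = "s", x = c(0, 5000), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(tb, 10000)), 1L)
  tb2 <- data.frame(species_id = "s", x = c(0, 15000), y = c(0, 0))
  expect_equal(nrow(thin_occurrences(tb2, 10000)), 2L)
})

test_that("collinear records thin greedily from the sort origin", {
  tb <- data.frame(species_id = "s", x = c(0, 8000, 16000), y = 0)
  out <- thin_occurrences(tb, 10000)
  expect_equal(sort(out$x), c(0, 16000))
})

test_that("thinning is idempotent and per-species", {
  set.seed(11)
  tb <- data.frame(species_id = sample(c("a", "b", "c"), 200, replace = TRUE),
                   x = runif(200, 0, 50000), y = runif(200, 0, 50000))
  once <- thin_occurrences(tb, 10000)
  twice <- thin_occurrences(once, 10000)
  expect_identical(once, twice)
  # no two retained records of the same species are closer than the radius
  for (sp in unique(once$species_id)) {
    pts <- once[once$species_id == sp, ]
    if (nrow(pts) > 1) {
      d <- as.matrix(dist(pts[, c("x", "y")]))
      expect_gte(min(d[upper.tri(d)]), 10000)
    }
  }
})

test_that("species below the record floor are excluded", {
  tb <- data.frame(species_id = rep(c("four", "five"), c(4, 5)),
                   x = 1:9, y = 1:9)
  out <- filter_min_records(tb, 5)
  expect_setequal(unique(out$species_id), "five")
  set.seed(2)
  tb2 <- data.frame(species_id = sample(letters[1:6], 60, replace = TRUE),
                    x = runif(60), y = runif(60))
  out2 <- filter_min_records(tb2, 5)
  counts <- table(tb2$species_id)
  expect_setequal(unique(out2$species_id), names(counts)[counts >= 5])
})

test_that("record cleaning drops out-of-bounds points and duplicates", {
  spec <- grid_spec(10, 10, cell_size = 100)
  tb <- data.frame(species_id = c("a", "a", "a", "b"),
                   x = c(50, 50, -500, 150), y = c(50, 50, 50, 150))
  out <- clean_occurrences(tb, spec)
  lg <- attr(out, "cleaning_log")
  expect_equal(lg$out_of_bounds, 1L)
  expect_equal(lg$duplicates, 1L)
  expect_equal(nrow(out), 2L)
})

test_that("background sampling concentrates near a single occurrence", {
  spec <- grid_spec(20, 20, cell_size = 100)
  occ <- data.frame(species_id = "a", x = 1050, y = 1050)
  bs <- background_sample(occ, spec, n = 200, bandwidth = 100, seed = 1)
  d <- sqrt((bs$points$x - 1050)^2 + (bs$points$y - 1050)^2)
  expect_true(all(d <= 100 * sqrt(2)))  # within one cell of the occurrence
})

test_that("background sampling follows a 9:1 cluster weighting", {
  spec <- grid_spec(40, 40, cell_size = 100)
  # two tight clusters, 90 and 10 records
  occ <- data.frame(
    species_id = "a",
    x = c(rep(550, 90), rep(3550, 10)) + runif(100, -40, 40),
    y = c(rep(550, 90), rep(3550, 10)) + runif(100, -40, 40))
  bs <- background_sample(occ, spec, n = 4000, bandwidth = 300, seed = 2)
  near_big <- mean(bs$points$x < 2000)
  expect_gt(near_big, 0.85)
  expect_lt(near_big, 0.95)
})

test_that("background sampling is deterministic and validates inputs", {
  spec <- grid_spec(15, 15, cell_size = 100)
  occ <- data.frame(species_id = "a", x = c(250, 950), y = c(250, 950))
  a <- background_sample(occ, spec, n = 50, seed = 7)
  b <- background_sample(occ, spec, n = 50, seed = 7)
  expect_identical(a$points, b$points)
  expect_error(background_sample(occ[0, ], spec), "configuration error")
})

test_that("strictly monotone presence concentration yields a Boyce index of 1", {
  v <- (1:100) / 101
  bg <- v
  pres_up <- rep(v, times = 1:100)    # presence density increasing in suitability
  expect_equal(boyce_index(pres_up, bg), 1)
  pres_down <- rep(v, times = 100:1)
  expect_equal(boyce_index(pres_down, bg), -1)
})

test_that("the Boyce index is invariant under monotone suitability transforms", {
  set.seed(13)
  bg <- runif(500)
  pres <- rbeta(60, 4, 1.5)
  base <- boyce_index(pres, bg)
  expect_identical(boyce_index(pres^3, bg^3), base)
  expect_identical(boyce_index(exp(5 * pres), exp(5 * bg)), base)
  expect_identical(boyce_index(qlogis(pres / 1.001), qlogis(bg / 1.001)), base)
})

test_that("a hand-built five-window case reproduces the P/E Spearman", {
  bg <- seq(0.01, 1, by = 0.01)      # ECDF of bg at its own values: 0.01..1
  pres <- c(0.32, 0.77, 0.92)
  # windows (half-width 0.25) at centres 0, .25, .5, .75, 1:
  # E = 25, 50, 51, 51, 26 (of 100); P = 0, 1/3, 1/3, 2/3, 2/3 (of 3)
  pe <- c(0, (1/3) / 0.50, (1/3) / 0.51, (2/3) / 0.51, (2/3) / 0.26)
  expected <- cor(pe, c(0, 0.25, 0.5, 0.75, 1), method = "spearman")
  expect_equal(boyce_index(pres, bg, n_bins = 5, window_frac = 0.5), expected)
})

test_that("constant suitability yields an undefined Boyce index", {
  expect_true(is.na(boyce_index(rep(0.5, 10), rep(0.5, 100))))
})

test_that("uniformly sampled presences give a near-zero Boyce index", {
  set.seed(20)
  cbis <- replicate(20, {
    bg <- runif(400)
    pres <- runif(40)
    boyce_index(pres, bg)
  })
  expect_lt(abs(mean(cbis, na.rm = TRUE)), 0.25)
})

test_that("a strong single-predictor niche is recovered by the fitted surface", {
  preds <- toy_predictors(40, seed = 3)
  truth <- niche_suitability(niche_spec("s", c(gradient = 3)), preds)
  pres <- sample_presences(truth, 120, seed = 5)
  bg <- uniform_background(preds$gradient$spec, 800, seed = 6)
  fit <- fit_sdm(pres, bg, preds, species_id = "s", seed = 1)
  rho <- cor(as.vector(fit$surface$values), as.vector(truth$values),
             method = "spearman")
  expect_gt(rho, 0.9)
  expect_gt(fit$cbi_mean, 0.25)
  expect_true(all(fit$surface$values >= 0 & fit$surface$values <= 1))
})

test_that("duplicated predictors leave the fitted surface unchanged", {
  preds <- toy_predictors(25, seed = 4)
  truth <- niche_suitability(niche_spec("s", c(gradient = 3)), preds)
  pres <- sample_presences(truth, 60, seed = 7)
  bg <- uniform_background(preds$gradient$spec, 300, seed = 8)
  f1 <- fit_sdm(pres, bg, preds, species_id = "s", seed = 2)
  preds_dup <- c(preds, list(gradient_copy = preds$gradient))
  f2 <- fit_sdm(pres, bg, preds_dup, species_id = "s", seed = 2)
  expect_equal(f1$surface$values, f2$surface$values, tolerance = 1e-10)
})

test_that("zero-variance predictors are dropped with a warning", {
  preds <- toy_predictors(25, seed = 9)
  preds$flat <- value_grid(preds$gradient$spec, 1)
  truth <- niche_suitability(niche_spec("s", c(gradient = 3)), preds)
  pres <- sample_presences(truth, 50, seed = 10)
  bg <- uniform_background(preds$gradient$spec, 200, seed = 11)
  expect_warning(fit <- fit_sdm(pres, bg, preds, seed = 3), "zero-variance")
  expect_s3_class(fit, "fitted_sdm")
})

test_that("model filtering applies the threshold inclusively", {
  mk <- function(id, cbi) structure(list(species_id = id, cbi_mean = cbi),
                                    class = "fitted_sdm")
  models <- list(mk("low", 0.24), mk("edge", 0.25), mk("high", 0.8),
                 mk("undef", NA_real_))
  kept <- filter_models(models)
  expect_setequal(vapply(kept, `[[`, "", "species_id"), c("edge", "high"))
  set.seed(14)
  cohort <- lapply(1:50, function(i) mk(paste0("m", i), runif(1, -0.5, 1)))
  kept2 <- filter_models(cohort)
  expect_equal(length(kept2),
               sum(vapply(cohort, `[[`, 0, "cbi_mean") >= 0.25))
})

test_that("vegetation-type assignment honours the woody savannah rule", {
  lookup <- data.frame(
    species_id = c("g1", "s1", "sw", "w1", "gs", "s2"),
    vegetation_types = c("grassland", "savannah", "savannah",
                         "woodland_forest", "grassland;savannah", "savannah"),
    woody_cerrado_sl = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  ts <- assign_vegetation_types(lookup$species_id, lookup)
  expect_equal(ts[["g1"]], "grassland")
  expect_setequal(ts[["sw"]], c("savannah", "woodland_forest"))
  expect_setequal(ts[["gs"]], c("grassland", "savannah"))
  counts <- table(unlist(ts))
  expect_equal(as.numeric(counts[c("grassland", "savannah",
                                   "woodland_forest")]), c(2, 4, 2))
  expect_warning(out <- assign_vegetation_types(c("g1", "ghost"), lookup),
                 "absent")
  expect_false("ghost" %in% names(out))
})

test_that("richness stacking sums surfaces within and across types", {
  spec <- grid_spec(5, 5)
  mk <- function(id, v) structure(
    list(species_id = id, cbi_mean = 0.5, surface = value_grid(spec, v)),
    class = "fitted_sdm")
  models <- list(mk("a", 1), mk("b", 1), mk("c", 1))
  sets <- list(a = "savannah", b = "savannah", c = c("savannah", "woodland_forest"))
  suppressWarnings(rich <- stack_richness(models, sets))
  expect_true(all(rich$savannah$values == 3))
  expect_true(all(rich$woodland_forest$values == 1))
  expect_true(all(rich$grassland$values == 0))

  # cellwise sum equals the elementwise oracle for varied surfaces
  set.seed(15)
  models2 <- lapply(1:10, function(i)
    mk(paste0("m", i), matrix(runif(25), 5, 5)))
  sets2 <- setNames(rep(list("grassland"), 10), paste0("m", 1:10))
  suppressWarnings(rich2 <- stack_richness(models2, sets2))
  oracle <- Reduce(`+`, lapply(models2, function(m) m$surface$values))
  expect_equal(rich2$grassland$values, oracle, tolerance = 1e-12)
  expect_true(all(rich2$grassland$values <= 10))
  # binary mode counts thresholded surfaces
  suppressWarnings(richb <- stack_richness(models2, sets2, mode = "binary",
                                           threshold = 0.5))
  oracleb <- Reduce(`+`, lapply(models2, function(m)
    (m$surface$values >= 0.5) * 1))
  expect_equal(richb$grassland$values, oracleb)
})

test_that("richness is additive over disjoint species subsets", {
  spec <- grid_spec(4, 4)
  mk <- function(id, v) structure(
    list(species_id = id, cbi_mean = 0.5, surface = value_grid(spec, v)),
    class = "fitted_sdm")
  set.seed(16)
  models <- lapply(1:6, function(i) mk(paste0("m", i), matrix(runif(16), 4, 4)))
  sets <- setNames(rep(list("savannah"), 6), paste0("m", 1:6))
  suppressWarnings(all6 <- stack_richness(models, sets)$savannah$values)
  suppressWarnings(first3 <- stack_richness(models[1:3], sets[1:3])$savannah$values)
  suppressWarnings(last3 <- stack_richness(models[4:6], sets[4:6])$savannah$values)
  expect_equal(first3 + last3, all6, tolerance = 1e-12)
})
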