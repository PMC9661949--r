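test_that("Box-Cox reduces to linear and log cases", {
  lin <- boxcox_transform(c(1, 2, 3), lambda = 1)
  expect_equal(lin$values, c(0, 1, 2))
  lg <- boxcox_transform(c(1, exp(1), exp(2)), lambda = 0)
  expect_equal(lg$values, c(0, 1, 2))
  expect_error(boxcox_transform(c(-1, 2)), "domain error")
})

test_that("estimated lambda matches a fine grid-search oracle", {
  set.seed(61)
  for (i in 1:5) {
    x <- exp(rnorm(300, meanlog <- runif(1, 0, 1), runif(1, 0.3, 0.8)))
    est <- boxcox_transform(x)$lambda
    expect_lt(abs(est - oracle_boxcox_lambda(x)), 0.01)
  }
})

test_that("estimated lambda agrees with the standard regression-based fit", {
  skip_if_not_installed("MASS")
  set.seed(62)
  x <- exp(rnorm(500, 1, 0.5))
  bc <- MASS::boxcox(x ~ 1, lambda = seq(-2, 2, 0.001), plotit = FALSE)
  expect_lt(abs(boxcox_transform(x)$lambda - bc$x[which.max(bc$y)]), 0.01)
})

test_that("the transform preserves rank order exactly", {
  set.seed(63)
  x <- rgamma(200, 2, 0.1)
  for (l in c(-1.5, 0, 0.33, 1, 2)) {
    y <- boxcox_transform(x, lambda = l)$values
    expect_identical(order(y), order(x))
  }
  y <- boxcox_transform(x)$values
  expect_identical(order(y), order(x))
})

test_that("min-max scaling maps to [0, 1] with a defined constant case", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(cs <- minmax_scale(c(3, 3, 3)), "constant")
  expect_equal(cs, c(0.5, 0.5, 0.5))
  set.seed(64)
  x <- rnorm(50)
  expect_equal(minmax_scale(x), (x - min(x)) / (max(x) - min(x)))
  expect_true(is.na(minmax_scale(c(1, NA, 3))[2]))
})

test_that("metric scaling shifts non-positive data to a unit minimum", {
  x <- c(-5, 0, 10)
  sm <- scale_metric(x)
  expect_equal(sm$shift, 6)
  expect_equal(sm$values[1], 0)
  expect_equal(sm$values[3], 1)
  pos <- scale_metric(c(2, 5, 9))
  expect_equal(pos$shift, 0)
})

test_that("combining metrics takes the equal-weight mean then rescales", {
  spec <- grid_spec(1, 4)
  # cells chosen so the pre-rescale extremes are 0 and 1: rescale is identity
  rich <- value_grid(spec, matrix(c(0, 0.4, 0.6, 1), 1, 4))
  conn <- value_grid(spec, matrix(c(0, 0.8, 0.2, 1), 1, 4))
  out <- combine_metrics(list(richness = rich, connectivity = conn))
  expect_equal(as.vector(out$values), c(0, 0.6, 0.4, 1))
  # three metrics: (0.2, 0.4, 0.9) averages to 0.5 before rescaling
  g3 <- list(value_grid(spec, matrix(c(0, 0.2, 1, 0.5), 1, 4)),
             value_grid(spec, matrix(c(0, 0.4, 1, 0.5), 1, 4)),
             value_grid(spec, matrix(c(0, 0.9, 1, 0.5), 1, 4)))
  out3 <- combine_metrics(g3)
  expect_equal(out3$values[1, 2], 0.5)
  # nodata in any metric voids the cell
  conn$values[1, 2] <- NA
  out_na <- combine_metrics(list(rich, conn))
  expect_true(is.na(out_na$values[1, 2]))
})

test_that("score classes apply strict thresholds", {
  v <- c(0, 0.5, 0.500001, 0.7, 0.700001, 0.75, 0.8, 0.800001, 1)
  cls <- classify_scores(v)
  expect_equal(as.vector(cls), c(0, 0, 1, 1, 2, 2, 2, 3, 3))
  expect_equal(attr(cls, "levels"),
               c("below", "medium", "high", "very_high"))
})

# end-to-end fixture for scoring: mixed-type restorable landscape
scoring_fixture <- function(seed = 71, n = 60) {
  scen <- landscape_scenario(seed = seed, spec = grid_spec(n, n))
  lc <- generate_landcover_pair(scen)
  rtype <- assign_restoration_type(lc$lc1985, lc$lc2018)
  spec <- lc$lc2018$spec
  set.seed(seed)
  rich <- lapply(VEG_TYPES, function(tp)
    value_grid(spec, matrix(runif(n * n, 0, 20), n, n)))
  names(rich) <- VEG_TYPES
  gain <- value_grid(spec, matrix(rnorm(n * n, 50, 30), n, n))
  conn <- native_fraction(lc$lc2018, window_spec(1.21))
  list(lc = lc, rtype = rtype, rich = rich, gain = gain, conn = conn)
}

test_that("hotspot scores are bounded, complete and typed", {
  fx <- scoring_fixture()
  hs <- score_hotspots(fx$rich, fx$gain, fx$conn, fx$rtype)
  for (tp in names(hs$scores)) {
    cells <- !is.na(fx$rtype$codes) & fx$rtype$codes == LC_CODES[[tp]]
    v <- hs$scores[[tp]]$values
    expect_true(all(!is.na(v[cells])))
    expect_true(all(is.na(v[!cells])))
    expect_true(all(v[cells] >= 0 & v[cells] <= 1))
    expect_equal(range(v[cells]), c(0, 1))
  }
  expect_setequal(names(hs$lambdas$grassland), c("richness", "connectivity"))
  expect_setequal(names(hs$lambdas$savannah),
                  c("richness", "net_gain", "connectivity"))
})

test_that("grassland scores are bit-invariant to net-gain perturbation", {
  fx <- scoring_fixture()
  hs1 <- score_hotspots(fx$rich, fx$gain, fx$conn, fx$rtype)
  gain2 <- value_grid(fx$gain$spec, fx$gain$values * 3 + 17)
  hs2 <- score_hotspots(fx$rich, gain2, fx$conn, fx$rtype)
  expect_identical(hs1$scores$grassland$values, hs2$scores$grassland$values)
  expect_false(identical(hs1$scores$savannah$values,
                         hs2$scores$savannah$values))
})

test_that("scores are invariant to positive rescaling of a raw metric", {
  fx <- scoring_fixture()
  hs1 <- score_hotspots(fx$rich, fx$gain, fx$conn, fx$rtype)
  rich2 <- fx$rich
  rich2$savannah <- value_grid(fx$rich$savannah$spec,
                               fx$rich$savannah$values * 4.2)
  hs2 <- score_hotspots(rich2, fx$gain, fx$conn, fx$rtype)
  cells <- !is.na(fx$rtype$codes) & fx$rtype$codes == LC_CODES[["savannah"]]
  expect_equal(hs1$scores$savannah$values[cells],
               hs2$scores$savannah$values[cells], tolerance = 1e-6)
})

test_that("anchored shifts absorb additive changes to a raw metric", {
  fx <- scoring_fixture()
  # anchor on the scored population: the savannah-cell minimum is set to 0
  # in both variants, so both are re-anchored to a minimum of exactly 1
  # before the transform and score identically
  sav <- !is.na(fx$rtype$codes) & fx$rtype$codes == LC_CODES[["savannah"]]
  m0 <- min(fx$gain$values[sav])
  g1 <- value_grid(fx$gain$spec, fx$gain$values - m0)
  g2 <- value_grid(fx$gain$spec, fx$gain$values - m0 - 40)
  hs1 <- score_hotspots(fx$rich, g1, fx$conn, fx$rtype)
  hs2 <- score_hotspots(fx$rich, g2, fx$conn, fx$rtype)
  expect_equal(hs1$scores$savannah$values, hs2$scores$savannah$values,
               tolerance = 1e-12)
})

test_that("combined scores are monotone in each scaled metric", {
  # anchor cells (all-0 and all-1) pin the final rescale, so raising one
  # metric at interior cells can only raise their combined score
  spec <- grid_spec(1, 6)
  a <- value_grid(spec, matrix(c(0, 1, 0.3, 0.5, 0.2, 0.8), 1, 6))
  b <- value_grid(spec, matrix(c(0, 1, 0.6, 0.1, 0.9, 0.4), 1, 6))
  b_up <- value_grid(spec, matrix(c(0, 1, 0.7, 0.3, 0.9, 0.6), 1, 6))
  s1 <- combine_metrics(list(a, b))
  s2 <- combine_metrics(list(a, b_up))
  expect_true(all(s2$values - s1$values >= -1e-12))
})

test_that("the combined map selects each cell's assigned-type score", {
  fx <- scoring_fixture()
  hs <- score_hotspots(fx$rich, fx$gain, fx$conn, fx$rtype)
  comb <- combined_hotspot(hs, fx$rtype, fx$lc$lc2018)
  for (tp in names(hs$scores)) {
    cells <- !is.na(fx$rtype$codes) & fx$rtype$codes == LC_CODES[[tp]]
    expect_identical(comb$fine$values[cells], hs$scores[[tp]]$values[cells])
  }
  expect_false(is.null(comb$coarse))
  expect_equal(comb$coarse$spec$cell_size, 5500)
})

test_that("aggregating a constant combined map returns the constant", {
  spec <- grid_spec(110, 110, cell_size = 100)
  rtype <- structure(list(spec = spec,
                          codes = matrix(LC_CODES[["savannah"]], 110, 110),
                          provenance = matrix(2L, 110, 110)),
                     class = "restoration_type_grid")
  hs <- structure(list(scores = list(savannah = value_grid(spec, 0.42)),
                       classes = list(), lambdas = list(), shifts = list()),
                  class = "hotspot_result")
  lc <- landcover_grid(spec, LC_CODES[["pasture"]])
  comb <- combined_hotspot(hs, rtype, lc)
  expect_true(all(abs(comb$coarse$values - 0.42) < 1e-12))
})
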