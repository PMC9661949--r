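test_that("inventory summaries report sample mean and n-1 s.d. per type", {
  inv1 <- data.frame(vegetation_type = "savannah", agb_mg_ha = 10)
  s1 <- inventory_summary(inv1)
  expect_equal(s1$mean_agb, 10)
  expect_true(is.na(s1$sd_agb))

  inv3 <- data.frame(vegetation_type = "grassland", agb_mg_ha = c(10, 20, 30))
  s3 <- inventory_summary(inv3)
  expect_equal(s3$mean_agb, 20)
  expect_equal(s3$sd_agb, 10)

  bad <- rbind(inv3, data.frame(vegetation_type = "swamp", agb_mg_ha = 5))
  expect_warning(sb <- inventory_summary(bad), "unknown vegetation type")
  expect_equal(nrow(sb), 1L)
})

test_that("root:shoot ratios are per-row BGB/AGB with per-type moments", {
  inv <- data.frame(vegetation_type = "savannah",
                    agb_mg_ha = c(10, 20), bgb_mg_ha = c(20, 40))
  rs <- root_shoot_stats(inv)
  expect_equal(rs$mean_rs, 2)
  expect_equal(rs$sd_rs, 0)
  expect_equal(rs$n_pairs, 2L)

  one <- data.frame(vegetation_type = "grassland", agb_mg_ha = 10,
                    bgb_mg_ha = 5)
  expect_equal(root_shoot_stats(one)$mean_rs, 0.5)
})

test_that("the synthetic inventory reproduces its calibrated statistics", {
  inv <- synthetic_plot_inventory(seed = 1)
  s <- inventory_summary(inv)
  expect_equal(s$mean_agb[match(c("grassland", "savannah", "woodland_forest"),
                                s$vegetation_type)],
               c(5.3, 24.3, 127.6), tolerance = 1e-9)
  expect_equal(s$sd_agb[match(c("grassland", "savannah", "woodland_forest"),
                              s$vegetation_type)],
               c(3.2, 16.2, 68.9), tolerance = 1e-9)
  rs <- root_shoot_stats(inv)
  expect_equal(rs$mean_rs[match(c("grassland", "savannah", "woodland_forest"),
                                rs$vegetation_type)],
               c(2.3, 1.8, 0.3), tolerance = 1e-9)
  expect_equal(rs$n_pairs[match(c("grassland", "savannah", "woodland_forest"),
                                rs$vegetation_type)], c(14L, 21L, 4L))
})

# small fixture: pasture field with two savannah reference regions
two_region_fixture <- function() {
  spec <- grid_spec(20, 20, cell_size = 100)
  c18 <- matrix(LC_CODES[["pasture"]], 20, 20)
  c18[1:4, 1:4] <- LC_CODES[["savannah"]]      # region A
  c18[17:20, 17:20] <- LC_CODES[["savannah"]]  # region B
  c85 <- matrix(LC_CODES[["pasture"]], 20, 20)
  lc18 <- landcover_grid(spec, c18)
  lc85 <- landcover_grid(spec, c85)
  agb <- matrix(NA_real_, 20, 20)
  agb[1:4, 1:4] <- 20
  agb[17:20, 17:20] <- 60
  agb[c18 == LC_CODES[["pasture"]]] <- 5
  list(spec = spec, lc85 = lc85, lc18 = lc18,
       agb = value_grid(spec, agb),
       rtype = assign_restoration_type(lc85, lc18))
}

test_that("localized AGB adopts the nearer reference region's mean", {
  fx <- two_region_fixture()
  loc <- localized_restoration_agb(fx$agb, fx$lc18, fx$rtype, min_refs = 10)
  # corner cells nearest each region take that region's uniform value
  expect_equal(loc$values[5, 5], 20)
  expect_equal(loc$values[16, 16], 60)
  # nearest-set oracle over every restorable cell
  refs <- which(!is.na(fx$lc18$codes) &
                  fx$lc18$codes == LC_CODES[["savannah"]])
  rr <- ((refs - 1L) %% 20) + 1L
  cc <- ((refs - 1L) %/% 20) + 1L
  rv <- fx$agb$values[refs]
  for (cell in which(!is.na(fx$rtype$codes) &
                       fx$rtype$codes == LC_CODES[["savannah"]])) {
    i <- ((cell - 1L) %% 20) + 1L
    j <- ((cell - 1L) %/% 20) + 1L
    d2 <- (rr - i)^2 + (cc - j)^2
    dk <- sort(d2, partial = 10)[10]
    expect_equal(loc$values[i, j], mean(rv[d2 <= dk]),
                 info = sprintf("cell (%d,%d)", i, j))
  }
})

test_that("uniform reference AGB propagates unchanged", {
  fx <- two_region_fixture()
  agb_u <- fx$agb
  agb_u$values[!is.na(fx$lc18$codes) &
                 fx$lc18$codes == LC_CODES[["savannah"]]] <- 40
  loc <- localized_restoration_agb(agb_u, fx$lc18, fx$rtype)
  restorable <- !is.na(fx$rtype$codes) &
    fx$rtype$codes == LC_CODES[["savannah"]]
  expect_true(all(loc$values[restorable] == 40))
})

test_that("insufficient references fall back to the global type mean, flagged", {
  spec <- grid_spec(8, 8, cell_size = 100)
  c18 <- matrix(LC_CODES[["pasture"]], 8, 8)
  c18[1, 1] <- LC_CODES[["savannah"]]
  lc18 <- landcover_grid(spec, c18)
  lc85 <- landcover_grid(spec, matrix(LC_CODES[["pasture"]], 8, 8))
  rtype <- assign_restoration_type(lc85, lc18)
  agb <- value_grid(spec, matrix(30, 8, 8))
  loc <- localized_restoration_agb(agb, lc18, rtype, min_refs = 10)
  restorable <- !is.na(rtype$codes) & rtype$codes == LC_CODES[["savannah"]]
  expect_true(all(loc$values[restorable] == 30))
  expect_true(all(attr(loc, "fallback")[restorable]))
})

test_that("missing reference vegetation for a type is a configuration error", {
  fx <- two_region_fixture()
  agb_na <- fx$agb
  agb_na$values[fx$lc18$codes == LC_CODES[["savannah"]]] <- NA
  expect_error(localized_restoration_agb(agb_na, fx$lc18, fx$rtype),
               "configuration error")
})

test_that("inventory adjustment is a rank-preserving quantile map", {
  fx <- two_region_fixture()
  set.seed(30)
  loc <- fx$agb
  restorable <- !is.na(fx$rtype$codes)
  loc$values[restorable] <- runif(sum(restorable), 0, 100)
  inv <- data.frame(vegetation_type = "savannah",
                    agb_mg_ha = c(10, 20, 30, 40, 50))
  adj <- adjust_to_inventory(loc, fx$rtype, inv)
  x <- loc$values[restorable]
  y <- adj$values[restorable]
  expect_equal(cor(x, y, method = "spearman"), 1)
  expect_true(all(y >= 10 & y <= 50))
  # the cell at the local median maps near the inventory median
  med_cell <- which.min(abs(x - median(x)))
  expect_lt(abs(y[med_cell] - 30), 2)
})

test_that("adjustment to the input's own distribution is near-identity", {
  fx <- two_region_fixture()
  restorable <- !is.na(fx$rtype$codes)
  set.seed(31)
  vals <- runif(sum(restorable), 10, 50)
  loc <- fx$agb
  loc$values[restorable] <- vals
  inv <- data.frame(vegetation_type = "savannah", agb_mg_ha = vals)
  adj <- adjust_to_inventory(loc, fx$rtype, inv)
  expect_equal(adj$values[restorable], vals, tolerance = 0.05)
})

test_that("sparse inventories skip adjustment with a warning", {
  fx <- two_region_fixture()
  inv <- data.frame(vegetation_type = "savannah", agb_mg_ha = c(10, 20))
  expect_warning(adj <- adjust_to_inventory(fx$agb, fx$rtype, inv),
                 "skipped")
  restorable <- !is.na(fx$rtype$codes)
  expect_equal(adj$values[restorable], fx$agb$values[restorable])
})

test_that("total biomass applies the type-mean root:shoot expansion", {
  spec <- grid_spec(2, 3, cell_size = 100)
  codes <- matrix(c(LC_CODES[["grassland"]], LC_CODES[["savannah"]],
                    LC_CODES[["woodland_forest"]], LC_CODES[["savannah"]],
                    LC_CODES[["grassland"]], LC_CODES[["savannah"]]), 2, 3)
  rtype <- structure(list(spec = spec, codes = codes,
                          provenance = matrix(2L, 2, 3)),
                     class = "restoration_type_grid")
  agb <- value_grid(spec, matrix(c(5, 10, 100, 10, 5, 10), 2, 3))
  rs <- data.frame(vegetation_type = VEG_TYPES, mean_rs = c(2.3, 1.8, 0.3))
  tot <- total_biomass(agb, rtype, rs)
  expect_equal(tot$values[1, 1], 16.5)   # 5 * (1 + 2.3)
  expect_equal(tot$values[2, 1], 28)     # 10 * (1 + 1.8)
  expect_equal(tot$values[1, 2], 130)    # 100 * (1 + 0.3)
  # zero ratio leaves AGB unchanged
  rs0 <- data.frame(vegetation_type = VEG_TYPES, mean_rs = c(0, 0, 0))
  expect_equal(total_biomass(agb, rtype, rs0)$values[1, 1], 5)
  expect_true(all(tot$values >= agb$values, na.rm = TRUE))
})

test_that("net gain subtracts the pasture baseline and can be negative", {
  spec <- grid_spec(2, 2)
  tot <- value_grid(spec, matrix(c(28, 130, 10, 14), 2, 2))
  ng <- net_gain(tot, 14)
  expect_equal(as.vector(ng$values), c(14, 116, -4, 0))
  ng2 <- net_gain(tot, value_grid(spec, 10))
  expect_equal(ng2$values[1, 2], 0)
})

test_that("stratified net gain recovers generator truth within 5%", {
  scen <- landscape_scenario(seed = 41, spec = grid_spec(120, 120),
                             patch_scale = 800)
  lc <- generate_landcover_pair(scen)
  agb <- generate_agb(lc$lc2018, seed = 41)$agb
  rtype <- assign_restoration_type(lc$lc1985, lc$lc2018)
  inv <- generate_inventory(seed = 41)$inventory
  rs <- root_shoot_stats(inv)
  loc <- localized_restoration_agb(agb, lc$lc2018, rtype)
  adj <- adjust_to_inventory(loc, rtype, inv)
  tot <- total_biomass(adj, rtype, rs)
  gain <- net_gain(tot, 14)
  truth_mean <- c(grassland = 5.3, savannah = 24.3, woodland_forest = 127.6)
  truth_rs <- c(grassland = 2.3, savannah = 1.8, woodland_forest = 0.3)
  for (tp in c("savannah", "woodland_forest")) {
    cells <- !is.na(rtype$codes) & rtype$codes == LC_CODES[[tp]]
    expected <- truth_mean[[tp]] * (1 + truth_rs[[tp]]) - 14
    got <- mean(gain$values[cells], na.rm = TRUE)
    expect_lt(abs(got - expected) / abs(expected), 0.05)
  }
})
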