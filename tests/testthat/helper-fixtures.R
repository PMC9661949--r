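# Shared fixtures: tiny grids, random landcover pairs, and brute-force
# oracles kept independent of the implementation paths they check.

small_spec <- function(n = 10, cell = 100) grid_spec(n, n, cell_size = cell)

lc_from_codes <- function(codes) {
  landcover_grid(small_spec(nrow(as.matrix(codes))), as.matrix(codes))
}

# random landcover pair on an n x n grid (codes drawn iid)
random_lc_pair <- function(n, seed) {
  set.seed(seed)
  spec <- grid_spec(n, n, cell_size = 100)
  c85 <- matrix(sample(LC_CODES, n * n, replace = TRUE), n, n)
  c18 <- matrix(sample(LC_CODES, n * n, replace = TRUE), n, n)
  list(lc1985 = landcover_grid(spec, c85), lc2018 = landcover_grid(spec, c18))
}

# Exhaustive nearest-reference oracle for restoration typing: all pairwise
# cell-centre distances, argmin with the class-priority tie-break.
oracle_assign <- function(lc1985, lc2018, max_search_radius = Inf) {
  spec <- lc1985$spec
  c85 <- lc1985$codes
  c18 <- lc2018$codes
  ref <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  ref[!is.na(c85) & c85 %in% NATIVE_CODES] <-
    c85[!is.na(c85) & c85 %in% NATIVE_CODES]
  ref[!is.na(c18) & c18 %in% NATIVE_CODES] <-
    c18[!is.na(c18) & c18 %in% NATIVE_CODES]
  refs <- which(!is.na(ref))
  priority <- unname(LC_CODES[c("savannah", "woodland_forest", "grassland")])
  out <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  max_sq <- (max_search_radius / spec$cell_size)^2
  for (i in seq_len(spec$n_rows)) for (j in seq_len(spec$n_cols)) {
    if (is.na(c18[i, j]) || c18[i, j] != LC_CODES[["pasture"]]) next
    if (!is.na(c85[i, j]) && c85[i, j] %in% NATIVE_CODES) {
      out[i, j] <- c85[i, j]
      next
    }
    if (!length(refs)) {
      out[i, j] <- RT_NOT_RESTORABLE
      next
    }
    rr <- ((refs - 1L) %% spec$n_rows) + 1L
    cc <- ((refs - 1L) %/% spec$n_rows) + 1L
    d2 <- (rr - i)^2 + (cc - j)^2
    dmin <- min(d2)
    if (dmin > max_sq) {
      out[i, j] <- RT_NOT_RESTORABLE
    } else {
      cand <- unique(ref[refs[d2 == dmin]])
      out[i, j] <- priority[priority %in% cand][1]
    }
  }
  out
}

# Brute-force moving-window native fraction for one cell
oracle_native_fraction_cell <- function(lc, i, j, half) {
  spec <- lc$spec
  rr <- max(1, i - half):min(spec$n_rows, i + half)
  cc <- max(1, j - half):min(spec$n_cols, j + half)
  block <- lc$codes[rr, cc, drop = FALSE]
  100 * sum(!is.na(block) & block %in% NATIVE_CODES) / length(block)
}

# Box-Cox profile log-likelihood grid-search oracle
oracle_boxcox_lambda <- function(x, step = 0.001) {
  lx <- log(x)
  n <- length(x)
  grid <- seq(-5, 5, by = step)
  ll <- vapply(grid, function(l) {
    y <- if (abs(l) < 1e-12) lx else (x^l - 1) / l
    -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * sum(lx)
  }, 0)
  grid[which.max(ll)]
}

# small aligned predictor set with one strong smooth gradient and one
# independent noise surface
toy_predictors <- function(n = 40, seed = 1) {
  set.seed(seed)
  spec <- grid_spec(n, n, cell_size = 100)
  grad <- outer(seq(-1.5, 1.5, length.out = n), seq(-1, 1, length.out = n), "+")
  noise <- matrix(rnorm(n * n), n, n)
  list(gradient = value_grid(spec, grad), noise = value_grid(spec, noise))
}

# sample presence points for a niche on toy predictors
sample_presences <- function(suit, n_pts, seed) {
  set.seed(seed)
  spec <- suit$spec
  cells <- sample.int(length(suit$values), n_pts, replace = TRUE,
                      prob = as.vector(suit$values))
  r <- ((cells - 1L) %% spec$n_rows) + 1L
  c <- ((cells - 1L) %/% spec$n_rows) + 1L
  xy <- cell_centre(spec, r, c)
  data.frame(x = xy[, 1], y = xy[, 2])
}

uniform_background <- function(spec, n_pts, seed) {
  set.seed(seed)
  cells <- sample.int(spec$n_rows * spec$n_cols, n_pts, replace = TRUE)
  r <- ((cells - 1L) %% spec$n_rows) + 1L
  c <- ((cells - 1L) %/% spec$n_rows) + 1L
  xy <- cell_centre(spec, r, c)
  data.frame(x = xy[, 1], y = xy[, 2])
}
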