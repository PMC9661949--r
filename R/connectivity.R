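# Moving-window native-vegetation fraction: the connectivity / landscape
# matrix metric, plus its window-size sensitivity analysis.

#' Define a square moving window from a target area
#'
#' Chooses the odd cell side whose square window area is nearest the
#' requested area (a 1.21 km2 request at 100 m cells realizes an 11 x 11
#' window, exactly 1.21 km2). The realized area is recorded alongside the
#' request.
#'
#' @param area_km2 Requested window area in km2 (positive).
#' @param cell_size Cell size in metres.
#' @return A `window_spec`: `area_km2` (requested), `side` (odd cell
#'   count), `realized_km2`.
#' @export
window_spec <- function(area_km2, cell_size = 100) {
  if (!is.finite(area_km2) || area_km2 <= 0)
    stop("configuration error: window area must be positive")
  side_exact <- sqrt(area_km2 * 1e6) / cell_size
  cand <- unique(pmax(1, c(2 * floor((side_exact - 1) / 2) + 1,
                           2 * floor((side_exact + 1) / 2) + 1)))
  realized <- (cand * cell_size)^2 / 1e6
  side <- cand[which.min(abs(realized - area_km2))]
  structure(list(area_km2 = area_km2, side = as.integer(side),
                 realized_km2 = (side * cell_size)^2 / 1e6),
            class = "window_spec")
}

# summed-area table with a zero top row / left column for O(1) box sums
.sat <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  cs <- m
  if (nr > 1L) for (i in 2:nr) cs[i, ] <- cs[i - 1L, ] + cs[i, ]
  if (nc > 1L) for (j in 2:nc) cs[, j] <- cs[, j - 1L] + cs[, j]
  s <- matrix(0, nr + 1L, nc + 1L)
  s[-1, -1] <- cs
  s
}

.box_sum <- function(s, r1, r2, c1, c2) {
  s[cbind(r2 + 1L, c2 + 1L)] - s[cbind(r1, c2 + 1L)] -
    s[cbind(r2 + 1L, c1)] + s[cbind(r1, c1)]
}

#' Moving-window native vegetation fraction
#'
#' For every cell, the percentage of cells within the centred square
#' window whose current landcover is native (grassland, savannah or
#' woodland & forest). Edge cells use the truncated window with its actual
#' in-grid cell count as denominator, so edge percentages remain
#' interpretable. Values lie in `[0, 100]`.
#'
#' @param lc2018 Current [landcover_grid()].
#' @param window A [window_spec()] (or a number, taken as area in km2).
#' @return A [value_grid()] of native cover percentages.
#' @export
native_fraction <- function(lc2018, window = window_spec(1.21)) {
  stopifnot(inherits(lc2018, "landcover_grid"))
  if (is.numeric(window)) window <- window_spec(window, lc2018$spec$cell_size)
  spec <- lc2018$spec
  if (window$side > min(spec$n_rows, spec$n_cols))
    stop("window side exceeds grid dimensions")
  h <- (window$side - 1L) %/% 2L
  native <- (!is.na(lc2018$codes) & lc2018$codes %in% NATIVE_CODES) * 1
  s <- .sat(native)
  rows <- row(native)
  cols <- col(native)
  r1 <- pmax(1L, rows - h)
  r2 <- pmin(spec$n_rows, rows + h)
  c1 <- pmax(1L, cols - h)
  c2 <- pmin(spec$n_cols, cols + h)
  counts <- .box_sum(s, as.vector(r1), as.vector(r2),
                     as.vector(c1), as.vector(c2))
  denom <- (as.vector(r2) - as.vector(r1) + 1) *
    (as.vector(c2) - as.vector(c1) + 1)
  value_grid(spec, matrix(100 * counts / denom, spec$n_rows, spec$n_cols))
}

#' Window-size sensitivity of downstream scores
#'
#' Recomputes the native-fraction layer for each requested window area,
#' pushes each through the supplied downstream scoring function, and
#' reports the Spearman rank-correlation matrix of the resulting scores
#' over the cells scored in every run — quantifying how sensitive the
#' prioritization is to the window-scale choice.
#'
#' @param lc2018 Current [landcover_grid()].
#' @param areas Numeric vector (length >= 2) of window areas in km2.
#' @param score_fun Function mapping a connectivity [value_grid()] to a
#'   score [value_grid()] (defaults to identity, i.e. the connectivity
#'   metric itself is compared).
#' @return List with `windows` (realized [window_spec()]s), `grids`
#'   (per-window score grids) and `correlation` (Spearman matrix; `NA`
#'   where undefined, e.g. constant scores).
#' @export
window_sensitivity <- function(lc2018, areas = c(0.25, 1.21, 9.61),
                               score_fun = identity) {
  if (length(areas) < 2L) stop("need >= 2 window areas")
  specs <- lapply(areas, window_spec, cell_size = lc2018$spec$cell_size)
  grids <- lapply(specs, function(w) score_fun(native_fraction(lc2018, w)))
  k <- length(grids)
  cm <- matrix(NA_real_, k, k,
               dimnames = list(sprintf("%g", areas), sprintf("%g", areas)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- as.vector(grids[[i]]$values)
    b <- as.vector(grids[[j]]$values)
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) >= 2L && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0)
      cm[i, j] <- suppressWarnings(
        stats::cor(a[ok], b[ok], method = "spearman"))
  }
  list(windows = specs, grids = grids, correlation = cm)
}
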