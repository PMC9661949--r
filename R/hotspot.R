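# Hotspot scoring: Box-Cox normalization, 0-1 scaling, equal-weight
# combination of the per-type metrics, threshold classification, and the
# combined map across vegetation types.

#' Box-Cox power transform
#'
#' `y = (x^lambda - 1) / lambda` for `lambda != 0` and `y = log(x)` at
#' `lambda = 0`; strictly increasing in `x`, so rank order is preserved
#' exactly. When `lambda` is not supplied it is estimated by maximizing
#' the Box-Cox profile log-likelihood
#' `-n/2 log(sigma_hat^2(lambda)) + (lambda - 1) sum(log x)` over
#' `[-5, 5]`. Values must be strictly positive; shift non-positive data
#' first (see [scale_metric()]).
#'
#' @param values Strictly positive numeric vector (`NA` allowed,
#'   preserved).
#' @param lambda Optional fixed exponent; estimated when `NULL`.
#' @return List with `values` (transformed) and `lambda`.
#' @export
boxcox_transform <- function(values, lambda = NULL) {
  fin <- !is.na(values)
  x <- values[fin]
  if (!length(x)) stop("no finite values to transform")
  if (any(x <= 0))
    stop("domain error: Box-Cox requires strictly positive values")
  if (is.null(lambda)) {
    lx <- log(x)
    n <- length(x)
    profile_ll <- function(l) {
      y <- if (abs(l) < 1e-12) lx else (x^l - 1) / l
      s2 <- mean((y - mean(y))^2)
      -n / 2 * log(s2) + (l - 1) * sum(lx)
    }
    if (stats::sd(x) == 0) {
      lambda <- 1  # constant input: any lambda is profile-equivalent
    } else {
      opt <- stats::optimize(profile_ll, interval = c(-5, 5), maximum = TRUE,
                             tol = 1e-6)
      lambda <- opt$maximum
    }
  }
  out <- values
  out[fin] <- if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
  list(values = out, lambda = lambda)
}

#' Normalize and scale a raw metric for scoring
#'
#' The per-metric scoring pipeline: shift by `1 - min(x)` when any value
#' is non-positive (net biomass gain can be negative, connectivity can be
#' zero), Box-Cox transform with estimated lambda, then min-max scale to
#' `[0, 1]`. Strictly monotone, so cell ranking is untouched.
#'
#' @param values Numeric vector (the metric over the scored cells).
#' @param lambda Optional fixed Box-Cox exponent.
#' @return List with `values` in `[0, 1]`, `lambda`, `shift`.
#' @export
scale_metric <- function(values, lambda = NULL) {
  fin <- values[!is.na(values)]
  if (!length(fin)) stop("no finite values to scale")
  shift <- if (min(fin) <= 0) 1 - min(fin) else 0
  bc <- boxcox_transform(values + shift, lambda = lambda)
  list(values = minmax_scale(bc$values), lambda = bc$lambda, shift = shift)
}

#' Combine scaled metrics into one score
#'
#' Cellwise unweighted mean over the type's scaled metric grids (two for
#' grassland, three otherwise), min-max rescaled to `[0, 1]`. A cell
#' missing any metric is nodata (missing information voids the cell
#' rather than reweighting it).
#'
#' @param stack Named list of aligned, pre-scaled metric [value_grid()]s.
#' @return Combined score [value_grid()] in `[0, 1]`.
#' @export
combine_metrics <- function(stack) {
  stopifnot(length(stack) >= 1L)
  spec <- stack[[1]]$spec
  for (g in stack) .check_aligned(stack[[1]], g, "metric grids")
  acc <- matrix(0, spec$n_rows, spec$n_cols)
  for (g in stack) acc <- acc + g$values  # NA propagates
  mean_v <- acc / length(stack)
  value_grid(spec, matrix(minmax_scale(as.vector(mean_v)),
                          spec$n_rows, spec$n_cols))
}

#' Classify hotspot scores
#'
#' Strict thresholds on the final `[0, 1]` score: `below` (<= 0.5),
#' `medium` (> 0.5), `high` (> 0.7), `very_high` (> 0.8).
#'
#' @param score Score [value_grid()] or numeric vector.
#' @return Same shape, with integer classes 0-3 and a `levels` attribute
#'   `c("below", "medium", "high", "very_high")`.
#' @export
classify_scores <- function(score) {
  v <- if (inherits(score, "value_grid")) score$values else score
  cls <- (v > 0.5) + (v > 0.7) + (v > 0.8)
  attr(cls, "levels") <- c("below", "medium", "high", "very_high")
  if (inherits(score, "value_grid")) {
    g <- value_grid(score$spec, cls)
    attr(g, "levels") <- attr(cls, "levels")
    g
  } else cls
}

#' Score restoration hotspots per vegetation type
#'
#' For each vegetation type, restricts the metric layers to the restorable
#' cells assigned to that type, normalizes each metric with
#' [scale_metric()] (Box-Cox lambda estimated per metric per type), and
#' combines them with equal weight via [combine_metrics()]. Net biomass
#' gain is excluded for grassland, where conversion from planted pasture
#' is assumed to change biomass stocks negligibly; grassland scores are
#' therefore bit-invariant to the net-gain layer. Climate risk is, by
#' design, not an input here.
#'
#' @param richness Named list over [VEG_TYPES] of richness
#'   [value_grid()]s (from [stack_richness()]).
#' @param net_gain_grid Net-gain [value_grid()] (from [net_gain()]).
#' @param connectivity_grid Connectivity [value_grid()] (from
#'   [native_fraction()]).
#' @param rtype `restoration_type_grid`.
#' @return A `hotspot_result`: per-type `scores` and `classes`
#'   ([value_grid()]s), per-type/metric `lambdas` and `shifts`.
#' @export
score_hotspots <- function(richness, net_gain_grid, connectivity_grid, rtype) {
  stopifnot(inherits(rtype, "restoration_type_grid"))
  spec <- rtype$spec
  .check_aligned(connectivity_grid, rtype, "connectivity and rtype")
  scores <- list()
  classes <- list()
  lambdas <- list()
  shifts <- list()
  for (tp in VEG_TYPES) {
    code <- LC_CODES[[tp]]
    cells <- !is.na(rtype$codes) & rtype$codes == code
    if (!any(cells)) next
    metrics <- list(richness = richness[[tp]])
    if (tp != "grassland") metrics$net_gain <- net_gain_grid
    metrics$connectivity <- connectivity_grid
    scaled <- list()
    lambdas[[tp]] <- list()
    shifts[[tp]] <- list()
    for (mn in names(metrics)) {
      v <- metrics[[mn]]$values
      v[!cells] <- NA
      sm <- scale_metric(as.vector(v))
      lambdas[[tp]][[mn]] <- sm$lambda
      shifts[[tp]][[mn]] <- sm$shift
      scaled[[mn]] <- value_grid(spec, matrix(sm$values, spec$n_rows,
                                              spec$n_cols))
    }
    sc <- combine_metrics(scaled)
    scores[[tp]] <- sc
    classes[[tp]] <- classify_scores(sc)
  }
  structure(list(scores = scores, classes = classes, lambdas = lambdas,
                 shifts = shifts),
            class = "hotspot_result")
}

#' Combined hotspot map across vegetation types
#'
#' Assuming every restorable cell is restored to its assigned vegetation
#' type, each cell takes the hotspot score of that type; the fine map is
#' also block-aggregated (default 5.5 km) over the pasture cells for
#' display.
#'
#' @param result A `hotspot_result` from [score_hotspots()].
#' @param rtype `restoration_type_grid`.
#' @param lc2018 Current [landcover_grid()] (pasture selector for the
#'   aggregation); optional.
#' @param block_size Aggregation block in metres (default 5500).
#' @return List with `fine` (cellwise combined score [value_grid()]),
#'   `classes`, and `coarse` (aggregated score, `NULL` when `lc2018` is
#'   missing).
#' @export
combined_hotspot <- function(result, rtype, lc2018 = NULL, block_size = 5500) {
  stopifnot(inherits(result, "hotspot_result"),
            inherits(rtype, "restoration_type_grid"))
  spec <- rtype$spec
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  for (tp in names(result$scores)) {
    code <- LC_CODES[[tp]]
    cells <- !is.na(rtype$codes) & rtype$codes == code
    out[cells] <- result$scores[[tp]]$values[cells]
  }
  fine <- value_grid(spec, out)
  coarse <- NULL
  if (!is.null(lc2018)) {
    f <- block_size / spec$cell_size
    if (!isTRUE(all.equal(f, round(f)))) {
      # trim to the nearest integer cell multiple and record the choice
      block_size <- round(f) * spec$cell_size
    }
    coarse <- block_aggregate(fine, block_size, selector = lc2018,
                              selector_code = LC_CODES[["pasture"]])
  }
  list(fine = fine, classes = classify_scores(fine), coarse = coarse)
}
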