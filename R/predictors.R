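# Climatic and edaphic predictor derivation for the species distribution
# models: moisture-index family (from Priestley-Taylor potential
# evapotranspiration), minimum temperature of the coldest month (bio6),
# days above 25 degC, and a principal-component reduction of the edaphic
# variables.

# Priestley-Taylor constants. Delta uses the Tetens saturation vapour
# pressure form; ground heat flux is taken as zero.
.PT_GAMMA <- 0.066   # psychrometric constant, kPa / degC
.PT_LAMBDA <- 2.45   # latent heat of vaporization, MJ / kg

.svp_slope <- function(temp_c) {
  es <- 0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
  4098 * es / (temp_c + 237.3)^2
}

#' Priestley-Taylor potential evapotranspiration
#'
#' `PET = alpha * Delta / (Delta + gamma) * Rn / lambda`, with `Delta` the
#' slope of the saturation-vapour-pressure curve at the mean temperature
#' (Tetens form), `gamma = 0.066` kPa/degC, `lambda = 2.45` MJ/kg and zero
#' ground heat flux. Net radiation in W/m2 is converted to MJ/m2/day
#' (x 0.0864) and the daily rate to a monthly total. Negative net
#' radiation is clamped to zero with a warning; `alpha = 1` gives the
#' equilibrium rate, the default `alpha = 1.26` the standard
#' Priestley-Taylor rate.
#'
#' @param net_radiation Net radiation, W/m2 (scalar, vector or
#'   [value_grid()]).
#' @param mean_temp Mean temperature, degC (same shape).
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @param days_in_month Days used to scale to a monthly total (default
#'   30.44, the mean month).
#' @return PET in mm/month, same shape as the inputs.
#' @export
priestley_taylor_pet <- function(net_radiation, mean_temp, alpha = 1.26,
                                 days_in_month = 30.44) {
  grid_in <- inherits(net_radiation, "value_grid")
  rn <- if (grid_in) net_radiation$values else net_radiation
  tt <- if (inherits(mean_temp, "value_grid")) mean_temp$values else mean_temp
  if (any(tt < -50 | tt > 60, na.rm = TRUE))
    stop("mean_temp outside plausible range (-50, 60) degC")
  if (any(rn < 0, na.rm = TRUE)) {
    warning("negative net radiation clamped to 0")
    rn <- pmax(rn, 0)
  }
  delta <- .svp_slope(tt)
  pet_day <- alpha * delta / (delta + .PT_GAMMA) * (rn * 0.0864) / .PT_LAMBDA
  pet <- pet_day * days_in_month
  if (grid_in) value_grid(net_radiation$spec, pet) else pet
}

#' Moisture index
#'
#' Ratio of precipitation to (equilibrium) evapotranspiration over the
#' same period. Cells with `pet <= 0` are undefined and returned as
#' nodata, never infinity.
#'
#' @param precip Precipitation, mm per period.
#' @param pet Potential evapotranspiration, mm per period.
#' @return Dimensionless moisture index, same shape.
#' @export
moisture_index <- function(precip, pet) {
  grid_in <- inherits(precip, "value_grid")
  p <- if (grid_in) precip$values else precip
  e <- if (inherits(pet, "value_grid")) pet$values else pet
  mi <- p / e
  mi[!is.na(e) & e <= 0] <- NA_real_
  if (grid_in) value_grid(precip$spec, mi) else mi
}

#' Dry-season length
#'
#' Number of months with a moisture index strictly below 1.
#'
#' @param monthly_mi Either a numeric vector of 12 monthly MI values or a
#'   list of 12 monthly [value_grid()]s.
#' @return Integer count in `[0, 12]` (or a [value_grid()] of counts).
#' @export
dry_season_length <- function(monthly_mi) {
  if (is.list(monthly_mi) && inherits(monthly_mi[[1]], "value_grid")) {
    stopifnot(length(monthly_mi) == 12L)
    acc <- Reduce(`+`, lapply(monthly_mi, function(g) (g$values < 1) * 1))
    return(value_grid(monthly_mi[[1]]$spec, acc))
  }
  stopifnot(length(monthly_mi) == 12L)
  sum(monthly_mi < 1, na.rm = FALSE)
}

#' Minimum temperature of the coldest month (bio6)
#'
#' @param monthly_tmin Numeric vector of 12 monthly minimum temperatures,
#'   or a list of 12 monthly [value_grid()]s.
#' @return The minimum over months (scalar or [value_grid()]).
#' @export
bioclim_bio6 <- function(monthly_tmin) {
  if (is.list(monthly_tmin) && inherits(monthly_tmin[[1]], "value_grid")) {
    stopifnot(length(monthly_tmin) == 12L)
    acc <- Reduce(pmin, lapply(monthly_tmin, `[[`, "values"))
    return(value_grid(monthly_tmin[[1]]$spec, acc))
  }
  stopifnot(length(monthly_tmin) == 12L)
  min(monthly_tmin)
}

# cosine interpolation of a monthly climatology to a 365-day daily series
.daily_from_monthly <- function(monthly, n_days = 365L) {
  mids <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)) -
    c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) / 2
  xs <- c(mids[12] - 365, mids, mids[1] + 365)
  ys <- c(monthly[12], monthly, monthly[1])
  days <- seq_len(n_days) - 0.5
  out <- numeric(n_days)
  for (d in seq_len(n_days)) {
    i <- findInterval(days[d], xs)
    t <- (days[d] - xs[i]) / (xs[i + 1] - xs[i])
    w <- (1 - cos(pi * t)) / 2  # smooth within-month transition
    out[d] <- ys[i] * (1 - w) + ys[i + 1] * w
  }
  out
}

#' Days per year with maximum temperature above a threshold
#'
#' Counts days with daily maximum temperature strictly above `threshold`,
#' averaged over the years supplied. A daily series is used directly; a
#' 12-value monthly climatology is first interpolated to a 365-day series
#' with a smooth (cosine) within-month transition, and the result carries
#' attribute `interpolated = TRUE`.
#'
#' @param tmax Numeric vector: a daily series (length a multiple of 365)
#'   or a monthly climatology (length 12, interpolated).
#' @param threshold Threshold in degC (default 25).
#' @return Days per year above the threshold.
#' @export
days_above_threshold <- function(tmax, threshold = 25) {
  interpolated <- FALSE
  if (length(tmax) == 12L) {
    tmax <- .daily_from_monthly(tmax)
    interpolated <- TRUE
  }
  if (length(tmax) %% 365L != 0L)
    stop("tmax must be a 12-month climatology or whole years of daily values")
  n_years <- length(tmax) / 365L
  structure(sum(tmax > threshold) / n_years, interpolated = interpolated)
}

#' Fit a principal-component reduction of the edaphic variables
#'
#' Standardizes each variable to zero mean and unit variance (after
#' per-variable mean imputation of missing values; constant variables are
#' dropped with a warning) and retains the smallest number of axes whose
#' cumulative explained variance exceeds `variance_target`.
#'
#' @param table Numeric matrix or data.frame, sites x variables.
#' @param variance_target Cumulative explained-variance threshold
#'   (default 0.80).
#' @return An `edaphic_pca` object: loadings (rotation), explained-variance
#'   fractions, `n_axes`, and the standardization means/s.d.s needed to
#'   project new sites with [edaphic_pca_apply()].
#' @export
edaphic_pca_fit <- function(table, variance_target = 0.80) {
  x <- as.matrix(table)
  storage.mode(x) <- "double"
  if (ncol(x) < 2L || nrow(x) < 3L)
    stop("need >= 2 variables and >= 3 sites")
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d constant variable(s)", sum(!keep)))
    x <- x[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(x) < 2L) stop("fewer than 2 non-constant variables")
  mus <- colMeans(x)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- which(cumsum(evf) > variance_target)[1]
  structure(list(loadings = pc$rotation, explained = evf,
                 n_axes = n_axes, means = mus, sds = sds,
                 variance_target = variance_target,
                 variables = colnames(x)),
            class = "edaphic_pca")
}

#' Project sites onto fitted edaphic principal components
#'
#' Applies the stored standardization and loadings of an
#' [edaphic_pca_fit()] to new sites; exactly reproduces the training
#' scores on the training table.
#'
#' @param pca An `edaphic_pca` object.
#' @param table Sites x variables (must contain the fitted variables).
#' @param n_axes Number of axes to return (default: the retained axes).
#' @return Matrix of site scores, sites x `n_axes`.
#' @export
edaphic_pca_apply <- function(pca, table, n_axes = pca$n_axes) {
  x <- as.matrix(table)
  if (!is.null(colnames(x)) && !is.null(pca$variables))
    x <- x[, pca$variables, drop = FALSE]
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- pca$means[j]
  }
  z <- sweep(sweep(x, 2L, pca$means), 2L, pca$sds, "/")
  z %*% pca$loadings[, seq_len(n_axes), drop = FALSE]
}

#' Derive the full SDM predictor stack
#'
#' From monthly climatologies and edaphic variables, derives the five
#' climate predictors — annual moisture index, minimum monthly moisture
#' index, dry-season length, bio6, days above 25 degC — and the retained
#' edaphic principal-component axes as aligned surfaces.
#'
#' @param stack Output of [generate_predictor_stack()] or a list with the
#'   same structure (`precip`, `tmin`, `tmax`, `tmean`, `net_radiation`
#'   monthly [value_grid()] lists and `edaphic` grids).
#' @param alpha Priestley-Taylor coefficient (default 1.26).
#' @param n_axes Edaphic axes to retain; default chooses by the 80%
#'   explained-variance rule.
#' @return List with `predictors` (named list of [value_grid()]s:
#'   `annual_mi`, `min_monthly_mi`, `dry_season_length`, `bio6`,
#'   `days_above_25`, `edaphic_pc1` ...) and `pca` (the fitted
#'   [edaphic_pca_fit()] model).
#' @export
compute_predictor_stack <- function(stack, alpha = 1.26, n_axes = NULL) {
  spec <- stack$precip[[1]]$spec
  dim <- c(spec$n_rows, spec$n_cols)
  month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  pet <- lapply(1:12, function(m)
    priestley_taylor_pet(stack$net_radiation[[m]], stack$tmean[[m]],
                         alpha = alpha, days_in_month = month_days[m]))
  mi <- lapply(1:12, function(m) moisture_index(stack$precip[[m]], pet[[m]]))
  annual_p <- Reduce(`+`, lapply(stack$precip, `[[`, "values"))
  annual_pet <- Reduce(`+`, lapply(pet, `[[`, "values"))
  annual_mi <- annual_p / annual_pet
  annual_mi[annual_pet <= 0] <- NA_real_
  min_mi <- Reduce(pmin, lapply(mi, `[[`, "values"))
  dsl <- dry_season_length(mi)
  bio6 <- bioclim_bio6(stack$tmin)
  # days > 25 from the monthly tmax climatology, cellwise
  tmax_cells <- vapply(stack$tmax, function(g) as.vector(g$values),
                       numeric(prod(dim)))
  d25 <- apply(tmax_cells, 1L, function(mm)
    as.numeric(days_above_threshold(as.numeric(mm), 25)))
  ed_cells <- vapply(stack$edaphic, function(g) as.vector(g$values),
                     numeric(prod(dim)))
  colnames(ed_cells) <- names(stack$edaphic)
  pca <- edaphic_pca_fit(ed_cells)
  k <- if (is.null(n_axes)) pca$n_axes else n_axes
  scores <- edaphic_pca_apply(pca, ed_cells, n_axes = k)
  preds <- list(
    annual_mi = value_grid(spec, annual_mi),
    min_monthly_mi = value_grid(spec, min_mi),
    dry_season_length = dsl,
    bio6 = bio6,
    days_above_25 = value_grid(spec, matrix(d25, dim[1], dim[2]))
  )
  for (j in seq_len(k))
    preds[[sprintf("edaphic_pc%d", j)]] <-
      value_grid(spec, matrix(scores[, j], dim[1], dim[2]))
  list(predictors = preds, pca = pca)
}

#' Serialize a fitted edaphic PCA model to JSON
#'
#' Stores means, s.d.s and loadings so the exact transform can be
#' reapplied to new sites.
#'
#' @param pca An `edaphic_pca` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
edaphic_pca_write <- function(pca, path) {
  jsonlite::write_json(
    list(variables = pca$variables, means = unname(pca$means),
         sds = unname(pca$sds), explained = pca$explained,
         n_axes = pca$n_axes,
         loadings = apply(pca$loadings, 2L, identity, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
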