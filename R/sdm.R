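# Occurrence cleaning, presence-background distribution modelling with
# 5-fold cross-validation, continuous Boyce index evaluation, and stacking
# of per-vegetation-type species richness surfaces.

#' Clean an occurrence table against the study grid
#'
#' Applies the record-cleaning filters in order: in-bounds check against
#' the grid extent, exact duplicate removal (per species, after flooring
#' coordinates to `precision_m`), and a coordinate-precision floor. Each
#' filter's removal count is reported via `attr(, "cleaning_log")`.
#'
#' @param table Occurrence data.frame (`species_id`, `x`, `y`).
#' @param spec A [grid_spec()] defining the study extent.
#' @param precision_m Coordinates are floored to this precision before
#'   duplicate detection (default 1 m).
#' @return The cleaned table, with a `cleaning_log` attribute.
#' @export
clean_occurrences <- function(table, spec, precision_m = 1) {
  stopifnot(all(c("species_id", "x", "y") %in% names(table)))
  n0 <- nrow(table)
  rc <- locate_cells(spec, table$x, table$y)
  table <- table[!is.na(rc[, "row"]), , drop = FALSE]
  n_oob <- n0 - nrow(table)
  xq <- floor(table$x / precision_m)
  yq <- floor(table$y / precision_m)
  dup <- duplicated(paste(table$species_id, xq, yq))
  table <- table[!dup, , drop = FALSE]
  rownames(table) <- NULL
  attr(table, "cleaning_log") <- list(input = n0, out_of_bounds = n_oob,
                                      duplicates = sum(dup),
                                      retained = nrow(table))
  table
}

#' Spatially thin occurrence records
#'
#' Retains, per species, at most one record within `radius` of any other
#' retained record, reducing environmental sampling bias. Records are
#' processed greedily in (y, x, insertion-order) sort order, so the result
#' is deterministic; a record is kept iff it lies at distance `>= radius`
#' from every already-kept record of the same species. Thinning is
#' idempotent.
#'
#' @param table Occurrence data.frame (`species_id`, `x`, `y`) in
#'   projected metre coordinates.
#' @param radius Minimum allowed pairwise distance in metres (default
#'   10 km).
#' @return The thinned table.
#' @export
thin_occurrences <- function(table, radius = 10000) {
  stopifnot(all(c("species_id", "x", "y") %in% names(table)))
  if (!nrow(table)) return(table)
  r2 <- radius^2
  keep_all <- logical(nrow(table))
  for (sp in unique(table$species_id)) {
    idx <- which(table$species_id == sp)
    ord <- idx[order(table$y[idx], table$x[idx], idx)]
    kx <- numeric(0)
    ky <- numeric(0)
    for (i in ord) {
      if (!length(kx) ||
          min((kx - table$x[i])^2 + (ky - table$y[i])^2) >= r2) {
        keep_all[i] <- TRUE
        kx <- c(kx, table$x[i])
        ky <- c(ky, table$y[i])
      }
    }
  }
  out <- table[keep_all, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop species with too few records
#'
#' @param table Occurrence data.frame (`species_id`, `x`, `y`), normally
#'   post-thinning.
#' @param min_n Minimum records a species needs to be retained
#'   (default 5).
#' @return The filtered table.
#' @export
filter_min_records <- function(table, min_n = 5L) {
  if (!nrow(table)) return(table)
  counts <- table(table$species_id)
  keep <- names(counts)[counts >= min_n]
  out <- table[table$species_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample background points from an Epanechnikov kernel density
#'
#' Builds a collection-effort density surface by summing Epanechnikov
#' kernels `K(u) = 1 - u^2` (for `u <= 1`) centred on every occurrence
#' record of the full (all-species) table, then draws `n` background
#' points with cell probability proportional to that density. This makes
#' the background carry the same collection bias as the presences.
#'
#' @param all_occurrences Occurrence data.frame over all species.
#' @param spec A [grid_spec()].
#' @param n Number of background points (default 10000).
#' @param bandwidth Kernel radius in metres; default one fifth of the
#'   longer grid extent.
#' @param seed Integer seed.
#' @return List with `points` (data.frame `x`, `y`), and `density` (a
#'   [value_grid()]).
#' @export
background_sample <- function(all_occurrences, spec, n = 10000L,
                              bandwidth = NULL, seed = 1L) {
  if (!nrow(all_occurrences))
    stop("configuration error: need >= 1 occurrence to build the kernel")
  if (is.null(bandwidth))
    bandwidth <- 0.2 * max(spec$n_rows, spec$n_cols) * spec$cell_size
  set.seed(derive_seed(seed, "background"))
  h_cells <- bandwidth / spec$cell_size
  dens <- matrix(0, spec$n_rows, spec$n_cols)
  rc <- locate_cells(spec, all_occurrences$x, all_occurrences$y)
  ok <- !is.na(rc[, "row"])
  rc <- rc[ok, , drop = FALSE]
  if (!nrow(rc)) stop("configuration error: no occurrence inside the grid")
  hb <- ceiling(h_cells)
  for (i in seq_len(nrow(rc))) {
    r0 <- rc[i, "row"]
    c0 <- rc[i, "col"]
    rr <- max(1L, r0 - hb):min(spec$n_rows, r0 + hb)
    cc <- max(1L, c0 - hb):min(spec$n_cols, c0 + hb)
    u2 <- outer((rr - r0)^2, (cc - c0)^2, "+") / h_cells^2
    dens[rr, cc] <- dens[rr, cc] + pmax(0, 1 - u2)
  }
  if (all(dens <= 0))
    stop("configuration error: zero-density landscape")
  cells <- sample.int(length(dens), n, replace = TRUE, prob = as.vector(dens))
  r <- ((cells - 1L) %% spec$n_rows) + 1L
  c <- ((cells - 1L) %/% spec$n_rows) + 1L
  xy <- cell_centre(spec, r, c)
  jit <- matrix(stats::runif(2L * n, -0.5, 0.5) * spec$cell_size, ncol = 2L)
  list(points = data.frame(x = xy[, 1] + jit[, 1], y = xy[, 2] + jit[, 2]),
       density = value_grid(spec, dens))
}

#' Continuous Boyce index
#'
#' Evaluates a presence-only suitability model by comparing, across a
#' sliding suitability window, the share of evaluation presences (P) with
#' the share of background/expected points (E): a good model concentrates
#' presences in high-suitability windows, so P/E increases with
#' suitability. The index is the Spearman rank correlation between P/E and
#' the window centre, over windows with `E > 0`; it lies in `[-1, 1]` and
#' values above 0 beat random.
#'
#' Suitability is first mapped through the background empirical CDF, so
#' the index is exactly invariant under any strictly increasing transform
#' of the suitability scale; windows of width `window_frac` (of the
#' resulting `[0, 1]` range) are placed at `n_bins` regularly spaced
#' centres. Constant suitability gives an undefined index, returned as
#' `NA`.
#'
#' @param pres_suit Suitability at the evaluation presences (non-empty).
#' @param bg_suit Suitability over the background sample (non-empty).
#' @param n_bins Number of window centres (default 101).
#' @param window_frac Window width as a fraction of the suitability range
#'   (default 0.1).
#' @return The continuous Boyce index, or `NA` when undefined.
#' @export
boyce_index <- function(pres_suit, bg_suit, n_bins = 101L, window_frac = 0.1) {
  pres_suit <- pres_suit[!is.na(pres_suit)]
  bg_suit <- bg_suit[!is.na(bg_suit)]
  if (!length(pres_suit) || !length(bg_suit))
    stop("pres_suit and bg_suit must be non-empty")
  F <- stats::ecdf(bg_suit)
  up <- F(pres_suit)
  ub <- F(bg_suit)
  centres <- seq(0, 1, length.out = n_bins)
  half <- window_frac / 2
  eps <- 1e-9  # stabilizes window membership at exact quantile boundaries
  P <- vapply(centres, function(ct)
    mean(up >= ct - half - eps & up <= ct + half + eps), 0)
  E <- vapply(centres, function(ct)
    mean(ub >= ct - half - eps & ub <= ct + half + eps), 0)
  keep <- E > 0
  if (sum(keep) < 2L) return(NA_real_)
  pe <- P[keep] / E[keep]
  if (stats::sd(pe) == 0) return(NA_real_)
  suppressWarnings(stats::cor(pe, centres[keep], method = "spearman"))
}

# design matrix: standardized linear + quadratic features; exact duplicate
# feature columns are collapsed so duplicated predictors cannot split the
# ridge penalty
.sdm_features <- function(pred_mat, centers = NULL, scales = NULL,
                          keep = NULL) {
  feats <- cbind(pred_mat, pred_mat^2)
  colnames(feats) <- c(colnames(pred_mat), paste0(colnames(pred_mat), "^2"))
  if (is.null(centers)) {
    sds <- apply(feats, 2L, stats::sd)
    keep <- !duplicated(lapply(seq_len(ncol(feats)),
                               function(j) round(feats[, j], 12))) & sds > 0
    if (!any(keep)) stop("degenerate predictors: no usable feature")
    feats <- feats[, keep, drop = FALSE]
    centers <- colMeans(feats)
    scales <- apply(feats, 2L, stats::sd)
  } else {
    feats <- feats[, keep, drop = FALSE]
  }
  z <- sweep(sweep(feats, 2L, centers), 2L, scales, "/")
  list(z = z, centers = centers, scales = scales, keep = keep)
}

.ridge_fit <- function(z, y, penalty) {
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                        lambda = penalty / length(y), standardize = FALSE)
  b <- as.numeric(stats::coef(fit))
  names(b) <- c("(intercept)", colnames(z))
  b
}

.cloglog <- function(eta) pmin(1, pmax(0, 1 - exp(-exp(eta))))

#' Fit a presence-background species distribution model
#'
#' A penalized presence-background binomial model with linear and
#' quadratic features of every predictor and a fixed ridge penalty,
#' reported through the complementary log-log link so predictions lie in
#' `[0, 1]`. Presences are shuffled once with the run seed and split into
#' `folds` contiguous blocks; for each fold the model is trained on the
#' remaining presences (plus the full background) and scored on the
#' held-out presences with the continuous Boyce index. The reported
#' surface is refit on all presences. The learner is a documented
#' surrogate for a maximum-entropy fit with default features; the
#' evaluation, filtering and stacking around it do not depend on the
#' learner choice.
#'
#' Predictors with zero variance at the training points are dropped with a
#' warning; exactly duplicated features are collapsed, so a duplicated
#' predictor column yields the same surface as a single copy.
#'
#' @param presences Data.frame (`x`, `y`) of presence records for one
#'   species (at least `folds` rows).
#' @param background Data.frame (`x`, `y`) of background points.
#' @param predictors Named list of aligned predictor [value_grid()]s.
#' @param species_id Species identifier stored on the fit.
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed (fold shuffling).
#' @param penalty Ridge penalty on the summed log-likelihood scale
#'   (default 1.0).
#' @return A `fitted_sdm`: coefficients, per-fold and mean continuous
#'   Boyce index, and the prediction `surface` ([value_grid()] in
#'   `[0, 1]`).
#' @export
fit_sdm <- function(presences, background, predictors, species_id = "sp",
                    folds = 5L, seed = 1L, penalty = 1.0) {
  spec <- predictors[[1]]$spec
  if (nrow(presences) < folds)
    stop(sprintf("need >= %d presences for %d-fold cross-validation",
                 folds, folds))
  pred_cells <- vapply(predictors, function(g) as.vector(g$values),
                       numeric(spec$n_rows * spec$n_cols))
  colnames(pred_cells) <- names(predictors)
  at_points <- function(df) {
    rc <- locate_cells(spec, df$x, df$y)
    cell <- (rc[, "col"] - 1L) * spec$n_rows + rc[, "row"]
    pred_cells[cell, , drop = FALSE]
  }
  Xp <- at_points(presences)
  Xb <- at_points(background)
  okp <- stats::complete.cases(Xp)
  okb <- stats::complete.cases(Xb)
  Xp <- Xp[okp, , drop = FALSE]
  Xb <- Xb[okb, , drop = FALSE]
  if (nrow(Xp) < folds) stop("too few presences with predictor values")
  zero_var <- apply(rbind(Xp, Xb), 2L, stats::sd) == 0
  if (any(zero_var)) {
    warning(sprintf("dropping zero-variance predictor(s): %s",
                    paste(colnames(Xp)[zero_var], collapse = ", ")))
    Xp <- Xp[, !zero_var, drop = FALSE]
    Xb <- Xb[, !zero_var, drop = FALSE]
    pred_cells <- pred_cells[, !zero_var, drop = FALSE]
  }
  if (!ncol(Xp)) stop("degenerate predictors: none left after filtering")

  set.seed(derive_seed(seed, paste0("sdm_folds_", species_id)))
  ord <- sample.int(nrow(Xp))
  fold_id <- integer(nrow(Xp))
  fold_id[ord] <- rep(seq_len(folds), length.out = nrow(Xp))
  cbi_folds <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (sum(tr) < 2L || sum(!tr) < 1L) next
    Xtr <- rbind(Xp[tr, , drop = FALSE], Xb)
    ytr <- c(rep(1, sum(tr)), rep(0, nrow(Xb)))
    ft <- tryCatch(.sdm_features(Xtr), error = function(e) NULL)
    if (is.null(ft)) next
    b <- .ridge_fit(ft$z, ytr, penalty)
    pred_at <- function(X) {
      f <- .sdm_features(X, ft$centers, ft$scales, ft$keep)
      as.vector(b[1] + f$z %*% b[-1])
    }
    cbi_folds[k] <- boyce_index(.cloglog(pred_at(Xp[!tr, , drop = FALSE])),
                                .cloglog(pred_at(Xb)))
  }
  # final surface on all presences
  Xall <- rbind(Xp, Xb)
  yall <- c(rep(1, nrow(Xp)), rep(0, nrow(Xb)))
  ft <- .sdm_features(Xall)
  b <- .ridge_fit(ft$z, yall, penalty)
  fgrid <- .sdm_features(pred_cells, ft$centers, ft$scales, ft$keep)
  eta <- b[1] + fgrid$z %*% b[-1]
  surf <- matrix(.cloglog(as.vector(eta)), spec$n_rows, spec$n_cols)
  surf[matrix(!stats::complete.cases(pred_cells), spec$n_rows, spec$n_cols)] <- NA
  structure(list(species_id = species_id, coefficients = b,
                 cbi_folds = cbi_folds,
                 cbi_mean = if (all(is.na(cbi_folds))) NA_real_
                            else mean(cbi_folds, na.rm = TRUE),
                 n_presences = nrow(Xp),
                 surface = value_grid(spec, surf)),
            class = "fitted_sdm")
}

#' @export
print.fitted_sdm <- function(x, ...) {
  cat(sprintf("<fitted_sdm> %s: %d presences, mean CBI %.3f\n",
              x$species_id, x$n_presences, x$cbi_mean))
  invisible(x)
}

#' Discard models with a low continuous Boyce index
#'
#' @param models List of `fitted_sdm` objects.
#' @param cbi_min Minimum mean cross-validated Boyce index a model needs
#'   to be retained (default 0.25); models below the threshold, or with an
#'   undefined index, are discarded.
#' @return The retained models.
#' @export
filter_models <- function(models, cbi_min = 0.25) {
  keep <- vapply(models, function(m)
    !is.na(m$cbi_mean) && m$cbi_mean >= cbi_min, logical(1))
  models[keep]
}

#' Assign species to vegetation types
#'
#' Maps each species to one or more of the three restoration vegetation
#' types from a lookup table. Species flagged as woody savannah
#' (`woody_cerrado_sl`) additionally gain the woodland & forest type,
#' reflecting that dense woody savannah stands are mapped as forest in the
#' landcover legend. Species absent from the lookup are excluded with a
#' warning.
#'
#' @param species_ids Character vector of species to assign.
#' @param lookup Data.frame with columns `species_id`,
#'   `vegetation_types` (semicolon-separated subset of [VEG_TYPES]) and
#'   optionally `woody_cerrado_sl` (logical).
#' @return Named list: per species, a character vector of vegetation
#'   types.
#' @export
assign_vegetation_types <- function(species_ids, lookup) {
  stopifnot(all(c("species_id", "vegetation_types") %in% names(lookup)))
  missing <- setdiff(species_ids, lookup$species_id)
  if (length(missing))
    warning(sprintf("%d species absent from lookup and excluded: %s",
                    length(missing), paste(missing, collapse = ", ")))
  present <- intersect(species_ids, lookup$species_id)
  out <- lapply(present, function(sp) {
    row <- lookup[match(sp, lookup$species_id), ]
    types <- strsplit(as.character(row$vegetation_types), ";")[[1]]
    types <- trimws(types)
    if (!length(types) || !all(types %in% VEG_TYPES))
      stop(sprintf("invalid vegetation types for species '%s'", sp))
    woody <- "woody_cerrado_sl" %in% names(row) && isTRUE(as.logical(row$woody_cerrado_sl))
    if (woody) types <- union(types, "woodland_forest")
    types
  })
  stats::setNames(out, present)
}

#' Stack model surfaces into per-type species richness
#'
#' Sums, per vegetation type, the prediction surfaces of every retained
#' model whose species is assigned to that type — continuous stacking by
#' default, or binary stacking of thresholded surfaces. A species assigned
#' to two types contributes to both richness grids.
#'
#' @param models List of (filtered) `fitted_sdm` objects.
#' @param type_sets Named list from [assign_vegetation_types()].
#' @param mode `"continuous"` (sum of occurrence probabilities) or
#'   `"binary"` (sum of `surface >= threshold`).
#' @param threshold Binarization threshold for `mode = "binary"`.
#' @return Named list over [VEG_TYPES] of richness [value_grid()]s, with a
#'   `n_species` attribute per grid.
#' @export
stack_richness <- function(models, type_sets, mode = c("continuous", "binary"),
                           threshold = 0.5) {
  mode <- match.arg(mode)
  if (!length(models)) stop("empty model list")
  spec <- models[[1]]$surface$spec
  out <- list()
  for (tp in VEG_TYPES) {
    sel <- vapply(models, function(m)
      m$species_id %in% names(type_sets) &&
        tp %in% type_sets[[m$species_id]], logical(1))
    if (!any(sel)) {
      warning(sprintf("no model assigned to type '%s'; richness is zero", tp))
      g <- value_grid(spec, 0)
      attr(g, "n_species") <- 0L
      out[[tp]] <- g
      next
    }
    acc <- matrix(0, spec$n_rows, spec$n_cols)
    for (m in models[sel]) {
      s <- m$surface$values
      if (mode == "binary") s <- (s >= threshold) * 1
      acc <- acc + s
    }
    g <- value_grid(spec, acc)
    attr(g, "n_species") <- sum(sel)
    out[[tp]] <- g
  }
  out
}
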