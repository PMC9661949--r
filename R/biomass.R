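# Net total biomass (AGB + BGB) gain of restoration: per-type inventory
# statistics, root:shoot conversion, localized aboveground-biomass stocks
# and the pasture-baseline subtraction.

.check_inventory <- function(inv) {
  need <- c("vegetation_type", "agb_mg_ha")
  stopifnot(all(need %in% names(inv)))
  bad <- !inv$vegetation_type %in% VEG_TYPES
  if (any(bad)) {
    warning(sprintf("rejecting %d row(s) with unknown vegetation type: %s",
                    sum(bad), paste(unique(inv$vegetation_type[bad]),
                                    collapse = ", ")))
    inv <- inv[!bad, , drop = FALSE]
  }
  inv
}

#' Per-type aboveground-biomass summary of a plot inventory
#'
#' Sample mean and (n-1) standard deviation of plot AGB per vegetation
#' type; the s.d. is `NA` for single-plot types. Rows with unknown type
#' labels are rejected with a warning.
#'
#' @param inv Plot-inventory data.frame (`vegetation_type`, `agb_mg_ha`,
#'   optionally `bgb_mg_ha`).
#' @return Data.frame with columns `vegetation_type`, `n`, `mean_agb`,
#'   `sd_agb` (Mg/ha).
#' @export
inventory_summary <- function(inv) {
  inv <- .check_inventory(inv)
  if (!nrow(inv)) stop("no valid inventory rows")
  types <- intersect(VEG_TYPES, unique(inv$vegetation_type))
  do.call(rbind, lapply(types, function(tp) {
    x <- inv$agb_mg_ha[inv$vegetation_type == tp]
    data.frame(vegetation_type = tp, n = length(x), mean_agb = mean(x),
               sd_agb = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Per-type root:shoot ratio statistics
#'
#' Computes per-plot root:shoot ratios `R:S = BGB / AGB` over the paired
#' rows (both AGB and BGB measured; rows with non-positive AGB are
#' rejected), then the per-type mean, s.d. and pair count.
#'
#' @param inv Plot-inventory data.frame (`vegetation_type`, `agb_mg_ha`,
#'   `bgb_mg_ha`).
#' @return A `root_shoot_stats` data.frame with columns
#'   `vegetation_type`, `n_pairs`, `mean_rs`, `sd_rs`.
#' @export
root_shoot_stats <- function(inv) {
  stopifnot("bgb_mg_ha" %in% names(inv))
  inv <- .check_inventory(inv)
  paired <- !is.na(inv$bgb_mg_ha)
  bad_agb <- paired & inv$agb_mg_ha <= 0
  if (any(bad_agb)) {
    warning(sprintf("rejecting %d paired row(s) with non-positive AGB",
                    sum(bad_agb)))
    paired <- paired & !bad_agb
  }
  inv <- inv[paired, , drop = FALSE]
  if (!nrow(inv)) stop("no paired AGB/BGB rows")
  rs <- inv$bgb_mg_ha / inv$agb_mg_ha
  types <- intersect(VEG_TYPES, unique(inv$vegetation_type))
  out <- do.call(rbind, lapply(types, function(tp) {
    x <- rs[inv$vegetation_type == tp]
    data.frame(vegetation_type = tp, n_pairs = length(x), mean_rs = mean(x),
               sd_rs = if (length(x) > 1L) stats::sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("root_shoot_stats", class(out))
  out
}

#' Localized potential restoration AGB from remaining native vegetation
#'
#' For each restorable cell assigned type `t`, estimates the potential
#' mature AGB as the mean observed AGB over the nearest native cells of
#' type `t` in the current landcover: the search radius grows until at
#' least `min_refs` reference cells are found (distance ties at the final
#' radius are all included), capped at `max_radius`. Cells whose search
#' hits the cap fall back to the global type mean and are flagged.
#'
#' @param agb AGB [value_grid()] (Mg/ha).
#' @param lc2018 Current [landcover_grid()].
#' @param rtype `restoration_type_grid` from [assign_restoration_type()].
#' @param min_refs Minimum reference cells per estimate (default 10).
#' @param max_radius Search cap in metres (default 20 km).
#' @return A [value_grid()] of localized potential AGB on restorable
#'   cells, with attribute `fallback` (logical matrix marking global-mean
#'   cells).
#' @export
localized_restoration_agb <- function(agb, lc2018, rtype, min_refs = 10L,
                                      max_radius = 20000) {
  stopifnot(inherits(agb, "value_grid"), inherits(lc2018, "landcover_grid"),
            inherits(rtype, "restoration_type_grid"))
  .check_aligned(agb, lc2018, "agb and lc2018")
  .check_aligned(agb, rtype, "agb and rtype")
  spec <- agb$spec
  out <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  fallback <- matrix(FALSE, spec$n_rows, spec$n_cols)
  max_r2 <- (max_radius / spec$cell_size)^2
  for (tp in VEG_TYPES) {
    code <- LC_CODES[[tp]]
    target <- which(!is.na(rtype$codes) & rtype$codes == code)
    if (!length(target)) next
    refs <- which(!is.na(lc2018$codes) & lc2018$codes == code &
                    !is.na(agb$values))
    if (!length(refs))
      stop(sprintf("configuration error: no native '%s' cell with AGB", tp))
    ref_r <- ((refs - 1L) %% spec$n_rows) + 1L
    ref_c <- ((refs - 1L) %/% spec$n_rows) + 1L
    ref_v <- agb$values[refs]
    global_mean <- mean(ref_v)
    if (length(refs) < min_refs) {
      # not enough references anywhere: global-mean fallback for the type
      out[target] <- global_mean
      fallback[target] <- TRUE
      next
    }
    k <- min_refs
    tg_r <- ((target - 1L) %% spec$n_rows) + 1L
    tg_c <- ((target - 1L) %/% spec$n_rows) + 1L
    chunk <- max(1L, floor(4e6 / length(refs)))
    for (s in seq(1L, length(target), by = chunk)) {
      ii <- s:min(s + chunk - 1L, length(target))
      d2 <- outer(tg_r[ii], ref_r, "-")^2 + outer(tg_c[ii], ref_c, "-")^2
      for (j in seq_along(ii)) {
        dj <- d2[j, ]
        dk <- sort(dj, partial = k)[k]
        if (dk > max_r2) {
          out[target[ii[j]]] <- global_mean
          fallback[target[ii[j]]] <- TRUE
        } else {
          out[target[ii[j]]] <- mean(ref_v[dj <= dk])
        }
      }
    }
  }
  g <- value_grid(spec, out)
  attr(g, "fallback") <- fallback
  g
}

#' Adjust localized AGB to the empirical inventory distribution
#'
#' Per vegetation type, quantile-maps the cellwise distribution of
#' localized AGB onto the empirical distribution of the plot inventory,
#' preserving cell rank order exactly (a monotone map) and clipping the
#' output to the inventory range. This keeps the spatial ordering of the
#' remote-sensed stocks while enforcing a realistic distribution of
#' plot-scale values. Types with fewer than `min_rows` inventory plots
#' are left unadjusted with a warning.
#'
#' @param local_agb Localized AGB [value_grid()] from
#'   [localized_restoration_agb()].
#' @param rtype `restoration_type_grid` (defines each cell's type).
#' @param inv Plot-inventory data.frame.
#' @param min_rows Minimum inventory plots needed per type (default 5).
#' @return Adjusted [value_grid()].
#' @export
adjust_to_inventory <- function(local_agb, rtype, inv, min_rows = 5L) {
  stopifnot(inherits(local_agb, "value_grid"),
            inherits(rtype, "restoration_type_grid"))
  .check_aligned(local_agb, rtype, "local_agb and rtype")
  inv <- .check_inventory(inv)
  out <- local_agb$values
  for (tp in VEG_TYPES) {
    code <- LC_CODES[[tp]]
    cells <- which(!is.na(rtype$codes) & rtype$codes == code &
                     !is.na(local_agb$values))
    if (!length(cells)) next
    ref <- inv$agb_mg_ha[inv$vegetation_type == tp]
    if (length(ref) < min_rows) {
      warning(sprintf("type '%s': only %d inventory plot(s); adjustment skipped",
                      tp, length(ref)))
      next
    }
    x <- local_agb$values[cells]
    p <- (rank(x, ties.method = "average") - 0.5) / length(x)
    out[cells] <- stats::quantile(ref, probs = p, type = 7, names = FALSE)
  }
  value_grid(local_agb$spec, out)
}

#' Total biomass from AGB via root:shoot ratios
#'
#' Applies the per-type mean root:shoot ratio to the (adjusted) localized
#' restoration AGB: `total = AGB * (1 + R:S)` for the cell's assigned
#' vegetation type, giving the potential mature total biomass stock.
#'
#' @param agb AGB [value_grid()] on restorable cells (Mg/ha).
#' @param rtype `restoration_type_grid`.
#' @param rs A `root_shoot_stats` data.frame (or any data.frame with
#'   `vegetation_type` and `mean_rs`).
#' @return Total-biomass [value_grid()] (Mg/ha).
#' @export
total_biomass <- function(agb, rtype, rs) {
  stopifnot(inherits(agb, "value_grid"),
            inherits(rtype, "restoration_type_grid"),
            all(c("vegetation_type", "mean_rs") %in% names(rs)))
  .check_aligned(agb, rtype, "agb and rtype")
  out <- matrix(NA_real_, agb$spec$n_rows, agb$spec$n_cols)
  for (tp in VEG_TYPES) {
    code <- LC_CODES[[tp]]
    cells <- which(!is.na(rtype$codes) & rtype$codes == code &
                     !is.na(agb$values))
    if (!length(cells)) next
    m <- rs$mean_rs[match(tp, rs$vegetation_type)]
    if (is.na(m))
      stop(sprintf("no root:shoot mean available for type '%s'", tp))
    out[cells] <- agb$values[cells] * (1 + m)
  }
  value_grid(agb$spec, out)
}

#' Net total biomass gain of restoration
#'
#' Subtracts the total biomass stock of the planted pasture being replaced
#' from the potential restored total biomass; negative values (restoring
#' to low-biomass vegetation) are kept.
#'
#' @param restored_total Restored total-biomass [value_grid()] (Mg/ha).
#' @param pasture_total Pasture baseline: a scalar (Mg/ha, default
#'   `14 = 7 AGB x (1 + R:S 1.0)`) or an aligned [value_grid()].
#' @return Net-gain [value_grid()] defined on the restorable cells.
#' @export
net_gain <- function(restored_total, pasture_total = 14) {
  stopifnot(inherits(restored_total, "value_grid"))
  if (inherits(pasture_total, "value_grid")) {
    .check_aligned(restored_total, pasture_total,
                   "restored_total and pasture_total")
    base <- pasture_total$values
  } else {
    stopifnot(is.numeric(pasture_total), length(pasture_total) == 1L)
    base <- pasture_total
  }
  value_grid(restored_total$spec, restored_total$values - base)
}
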