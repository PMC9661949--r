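#' Assign a potential restoration vegetation type to pasture cells
#'
#' Every current (2018) pasture cell is a potential restoration site. Its
#' restoration vegetation type is assigned by two rules:
#'
#' 1. *Historical rule* — if the historical (1985) cover of the cell was a
#'    native class (grassland, savannah, woodland & forest), that class is
#'    assigned, provenance `historical`.
#' 2. *Proximity rule* — otherwise the class of the nearest reference cell
#'    is assigned (cell-centre Euclidean distance), provenance
#'    `proximity`. Reference cells are current native cells plus
#'    historically native cells; where a cell is native in both years
#'    with different classes the current class wins. Pasture cells with no
#'    reference cell within `max_search_radius` are marked not restorable.
#'
#' Distance ties between reference cells of different classes are broken
#' by the fixed priority savannah > woodland & forest > grassland. The
#' historical rule always overrides proximity, and the output does not
#' depend on cell visit order.
#'
#' @param lc1985,lc2018 Aligned [landcover_grid()]s (historical, current).
#' @param max_search_radius Maximum reference search distance in metres
#'   (default 50 km).
#' @return A `restoration_type_grid`: list with `spec`, `codes` (native
#'   class codes, [RT_NOT_RESTORABLE], or `NA` outside pasture) and
#'   `provenance` (see [PROVENANCE_CODES]).
#' @export
assign_restoration_type <- function(lc1985, lc2018, max_search_radius = 50000) {
  stopifnot(inherits(lc1985, "landcover_grid"), inherits(lc2018, "landcover_grid"))
  .check_aligned(lc1985, lc2018, "lc1985 and lc2018")
  spec <- lc1985$spec
  c85 <- lc1985$codes
  c18 <- lc2018$codes
  pasture <- !is.na(c18) & c18 == LC_CODES[["pasture"]]
  codes <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
  prov <- matrix(PROVENANCE_CODES[["none"]], spec$n_rows, spec$n_cols)

  # rule 1: historical native cover
  hist_native <- pasture & !is.na(c85) & c85 %in% NATIVE_CODES
  codes[hist_native] <- c85[hist_native]
  prov[hist_native] <- PROVENANCE_CODES[["historical"]]

  need <- pasture & !hist_native
  if (any(need)) {
    # reference class map: 2018 native wins over 1985 native
    ref <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
    is85 <- !is.na(c85) & c85 %in% NATIVE_CODES
    ref[is85] <- c85[is85]
    is18 <- !is.na(c18) & c18 %in% NATIVE_CODES
    ref[is18] <- c18[is18]
    max_sq <- (max_search_radius / spec$cell_size)^2
    # class priority for equidistant references
    priority <- LC_CODES[c("savannah", "woodland_forest", "grassland")]
    best_d <- matrix(Inf, spec$n_rows, spec$n_cols)
    best_c <- matrix(NA_integer_, spec$n_rows, spec$n_cols)
    for (cls in priority) {
      src <- !is.na(ref) & ref == cls
      if (!any(src)) next
      d <- .edt_squared(src)
      upd <- d < best_d  # strict: earlier (higher-priority) class keeps ties
      best_d[upd] <- d[upd]
      best_c[upd] <- cls
    }
    ok <- need & best_d <= max_sq & !is.na(best_c)
    codes[ok] <- best_c[ok]
    prov[ok] <- PROVENANCE_CODES[["proximity"]]
    codes[need & !ok] <- RT_NOT_RESTORABLE
  }
  structure(list(spec = spec, codes = codes, provenance = prov),
            class = "restoration_type_grid")
}

#' @export
print.restoration_type_grid <- function(x, ...) {
  lv <- c(NATIVE_CODES, not_restorable = RT_NOT_RESTORABLE)
  tb <- table(factor(x$codes, levels = lv, labels = names(lv)), useNA = "ifany")
  cat(sprintf("<restoration_type_grid> %d x %d\n", x$spec$n_rows, x$spec$n_cols))
  print(tb)
  invisible(x)
}

#' Share of restorable area per vegetation type
#'
#' Fractions of assigned restoration classes over all restorable cells
#' (cells assigned a native class; not-restorable and nodata cells are
#' excluded). With zero restorable cells every share is defined as 0.
#'
#' @param rtype A `restoration_type_grid` from [assign_restoration_type()].
#' @return Named numeric vector over [VEG_TYPES], summing to 1 when any
#'   cell is restorable.
#' @export
type_fractions <- function(rtype) {
  stopifnot(inherits(rtype, "restoration_type_grid"))
  v <- rtype$codes[!is.na(rtype$codes) & rtype$codes %in% NATIVE_CODES]
  out <- stats::setNames(numeric(length(VEG_TYPES)), VEG_TYPES)
  if (!length(v)) return(out)
  tb <- table(factor(v, levels = NATIVE_CODES, labels = VEG_TYPES))
  out[names(tb)] <- as.numeric(tb) / length(v)
  out
}
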