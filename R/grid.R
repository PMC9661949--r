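#' Landcover class codes
#'
#' Integer codes used throughout the package for the seven-class landcover
#' scheme: the three native restoration vegetation classes (grassland,
#' savannah, woodland & forest), the two converted classes (pasture,
#' agriculture), a catch-all `other`, and `NA` for nodata.
#'
#' @format Named integer vector of length 6.
#' @export
LC_CODES <- c(
  grassland       = 1L,
  savannah        = 2L,
  woodland_forest = 3L,
  pasture         = 4L,
  agriculture     = 5L,
  other           = 6L
)

#' Native vegetation class codes (grassland, savannah, woodland & forest)
#' @export
NATIVE_CODES <- LC_CODES[c("grassland", "savannah", "woodland_forest")]

#' Vegetation type labels in canonical order
#' @export
VEG_TYPES <- c("grassland", "savannah", "woodland_forest")

#' Restoration-type code for pasture cells with no reference vegetation in range
#' @export
RT_NOT_RESTORABLE <- -1L

#' Provenance codes for restoration-type assignment
#'
#' `HISTORICAL` marks cells typed from their own 1985 native cover,
#' `PROXIMITY` cells typed from the nearest reference cell, `NONE` cells
#' that received no assignment.
#' @export
PROVENANCE_CODES <- c(none = 0L, historical = 1L, proximity = 2L)

#' Grid specification
#'
#' Defines the raster geometry shared by every layer in an analysis: grid
#' dimensions, square cell size in metres, the lower-left corner of the
#' grid in a projected equal-area reference system, and a CRS identifier.
#' Cells are addressed 0-based as (row, col) with row 0 at the north edge;
#' all distances are computed between cell centres. Two grids are aligned
#' iff every field is equal.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres (positive).
#' @param origin_x,origin_y Coordinates of the lower-left grid corner (m).
#' @param crs_id Text identifier of the projected equal-area CRS. Identifiers
#'   that look geographic (e.g. `"EPSG:4326"`) are rejected because cell
#'   distances are Euclidean.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 100,
                      origin_x = 0, origin_y = 0,
                      crs_id = "ESRI:102033") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  if (!is.finite(cell_size) || cell_size <= 0)
    stop("cell_size must be positive")
  if (grepl("4326|4674|geographic|longlat", tolower(crs_id)))
    stop("geographic CRS not supported; supply a projected equal-area CRS")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_id = as.character(crs_id)),
    class = "grid_spec"
  )
}

#' Test whether two grid specifications are aligned
#'
#' @param a,b `grid_spec` objects.
#' @return `TRUE` iff all fields are equal.
#' @export
specs_aligned <- function(a, b) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y)) &&
    a$crs_id == b$crs_id
}

.check_aligned <- function(a, b, what = "grids") {
  sa <- if (inherits(a, "grid_spec")) a else a$spec
  sb <- if (inherits(b, "grid_spec")) b else b$spec
  if (!specs_aligned(sa, sb))
    stop(sprintf("alignment error: %s do not share the same grid_spec", what))
  invisible(TRUE)
}

#' Continuous-valued raster layer
#'
#' A single-band real-valued raster on a [grid_spec()]. Values are stored as
#' an `n_rows x n_cols` matrix with row 1 at the north edge; `NA` encodes
#' nodata and is excluded from every statistic.
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix (`n_rows x n_cols`) or a scalar to fill.
#' @return An object of class `value_grid`.
#' @export
value_grid <- function(spec, values = NA_real_) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), spec$n_rows, spec$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    stop("values matrix does not match grid dimensions")
  if (any(is.infinite(values)))
    stop("value_grid requires finite values or NA")
  structure(list(spec = spec, values = values), class = "value_grid")
}

#' Categorical landcover raster layer
#'
#' A single-band categorical raster over the seven-class landcover scheme
#' of [LC_CODES] (with `NA` for nodata). Same storage convention as
#' [value_grid()].
#'
#' @param spec A `grid_spec`.
#' @param codes Integer matrix of class codes, or a scalar code to fill.
#' @return An object of class `landcover_grid`.
#' @export
landcover_grid <- function(spec, codes = NA_integer_) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(codes) == 1L)
    codes <- matrix(as.integer(codes), spec$n_rows, spec$n_cols)
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != spec$n_rows || ncol(codes) != spec$n_cols)
    stop("codes matrix does not match grid dimensions")
  bad <- !is.na(codes) & !(codes %in% LC_CODES)
  if (any(bad))
    stop(sprintf("invalid landcover codes present: %s",
                 paste(unique(codes[bad]), collapse = ", ")))
  structure(list(spec = spec, codes = codes), class = "landcover_grid")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %g m, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_id))
  invisible(x)
}

#' @export
print.value_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<value_grid> %d x %d, %d nodata, range [%s, %s]\n",
              x$spec$n_rows, x$spec$n_cols, sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @export
print.landcover_grid <- function(x, ...) {
  tb <- table(factor(x$codes, levels = LC_CODES, labels = names(LC_CODES)),
              useNA = "ifany")
  cat(sprintf("<landcover_grid> %d x %d\n", x$spec$n_rows, x$spec$n_cols))
  print(tb)
  invisible(x)
}

#' Cell-centre coordinates
#'
#' Returns x/y coordinates of cell centres for 1-based (row, col) matrix
#' indices; row 1 is the north edge, so y decreases with row.
#'
#' @param spec A `grid_spec`.
#' @param row,col 1-based matrix indices (vectors of equal length).
#' @return A two-column matrix of (x, y) in metres.
#' @export
cell_centre <- function(spec, row, col) {
  cbind(x = spec$origin_x + (col - 0.5) * spec$cell_size,
        y = spec$origin_y + (spec$n_rows - row + 0.5) * spec$cell_size)
}

#' Locate points on the grid
#'
#' Maps projected coordinates to 1-based (row, col) indices; points outside
#' the grid get `NA` rows.
#'
#' @param spec A `grid_spec`.
#' @param x,y Coordinates in metres.
#' @return A two-column integer matrix (row, col) with `NA` for points
#'   outside the grid extent.
#' @export
locate_cells <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cell_size) + 1L
  row <- spec$n_rows - floor((y - spec$origin_y) / spec$cell_size)
  out <- col < 1L | col > spec$n_cols | row < 1L | row > spec$n_rows |
    !is.finite(x) | !is.finite(y)
  row[out] <- NA_integer_
  col[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}
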