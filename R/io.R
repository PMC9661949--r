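#' Write a raster layer to an ESRI ASCII grid
#'
#' Serializes a [value_grid()] or [landcover_grid()] to the plain-text ESRI
#' ASCII grid format (`.asc`) plus a small JSON sidecar (`<path>.json`)
#' carrying the CRS identifier and the layer kind, so that
#' [read_raster()] can reconstruct the object exactly. Integer layers
#' round-trip losslessly; continuous layers are written with 17 significant
#' digits so round-trip error is below 1e-6.
#'
#' @param grid A `value_grid` or `landcover_grid`.
#' @param path Output path (conventionally ending in `.asc`).
#' @param nodata Nodata sentinel written to the file (default -9999).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  if (!inherits(grid, c("value_grid", "landcover_grid")))
    stop("grid must be a value_grid or landcover_grid")
  spec <- grid$spec
  is_lc <- inherits(grid, "landcover_grid")
  m <- if (is_lc) grid$codes else grid$values
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10f", spec$origin_x),
    sprintf("yllcorner %.10f", spec$origin_y),
    sprintf("cellsize %.10f", spec$cell_size),
    sprintf("NODATA_value %g", nodata)
  )
  fmt <- if (is_lc) function(v) sprintf("%d", v) else function(v) sprintf("%.17g", v)
  body <- apply(m, 1L, function(r) {
    r2 <- ifelse(is.na(r), format(nodata), fmt(r))
    paste(r2, collapse = " ")
  })
  writeLines(c(hdr, body), path)
  jsonlite::write_json(
    list(kind = if (is_lc) "landcover" else "value", crs_id = spec$crs_id),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster layer from an ESRI ASCII grid
#'
#' Reads a single-band `.asc` raster written by [write_raster()] (or any
#' conforming ESRI ASCII grid). If a `<path>.json` sidecar declares the
#' layer a landcover grid, codes are validated against [LC_CODES];
#' otherwise a [value_grid()] is returned.
#'
#' @param path Path to the `.asc` file.
#' @param crs_id CRS identifier to use when no sidecar is present.
#' @return A `value_grid` or `landcover_grid`.
#' @export
read_raster <- function(path, crs_id = "ESRI:102033") {
  if (!file.exists(path)) stop(sprintf("input error: cannot read '%s'", path))
  lines <- readLines(path)
  if (length(lines) < 7L) stop("input error: truncated ASCII grid")
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2L) stop("input error: malformed ASCII grid header")
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("input error: missing ASCII grid header fields")
  kind <- "value"
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$crs_id)) crs_id <- meta$crs_id
    if (!is.null(meta$kind)) kind <- meta$kind
  }
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows)
    stop("input error: row count does not match header")
  vals <- vapply(body, function(l) {
    v <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    if (length(v) != n_cols) stop("input error: column count mismatch")
    v
  }, numeric(n_cols), USE.NAMES = FALSE)
  m <- t(vals)
  m[m == hdr$nodata_value] <- NA
  spec <- grid_spec(n_rows, n_cols, hdr$cellsize, hdr$xllcorner,
                    hdr$yllcorner, crs_id)
  if (identical(kind, "landcover")) landcover_grid(spec, m) else value_grid(spec, m)
}

#' Block-aggregate a raster over selected cells
#'
#' Aggregates a fine-resolution [value_grid()] to coarse blocks, averaging
#' only the fine cells whose landcover matches `selector_code` (typically
#' pasture, so coarse scores summarize potential restoration area only).
#' Blocks are anchored at the north-west corner; partial blocks at the
#' south/east edges average over the cells they actually contain. Blocks
#' with no matching (non-nodata) cell are nodata.
#'
#' @param grid `value_grid` to aggregate.
#' @param block_size Coarse cell size in metres; must be an integer
#'   multiple of the fine cell size.
#' @param selector Optional `landcover_grid` aligned with `grid`.
#' @param selector_code Class code cells must match to enter the mean
#'   (default pasture). Ignored when `selector` is `NULL`.
#' @return A coarse `value_grid`.
#' @export
block_aggregate <- function(grid, block_size, selector = NULL,
                            selector_code = LC_CODES[["pasture"]]) {
  stopifnot(inherits(grid, "value_grid"))
  spec <- grid$spec
  f <- block_size / spec$cell_size
  if (!isTRUE(all.equal(f, round(f))) || f < 1)
    stop("configuration error: block_size must be an integer multiple of cell_size")
  f <- as.integer(round(f))
  v <- grid$values
  if (!is.null(selector)) {
    stopifnot(inherits(selector, "landcover_grid"))
    .check_aligned(grid, selector, "grid and selector")
    v[is.na(selector$codes) | selector$codes != selector_code] <- NA
  }
  nrc <- ceiling(spec$n_rows / f)
  ncc <- ceiling(spec$n_cols / f)
  out <- matrix(NA_real_, nrc, ncc)
  ri <- ((seq_len(spec$n_rows) - 1L) %/% f) + 1L
  ci <- ((seq_len(spec$n_cols) - 1L) %/% f) + 1L
  grp <- (ci[col(v)] - 1L) * nrc + ri[row(v)]
  sums <- tapply(as.vector(v), grp, function(z) {
    z <- z[!is.na(z)]
    if (length(z)) mean(z) else NA_real_
  })
  out[as.integer(names(sums))] <- unlist(sums)
  cspec <- grid_spec(nrc, ncc, block_size,
                     origin_x = spec$origin_x,
                     origin_y = spec$origin_y + spec$n_rows * spec$cell_size -
                       nrc * block_size,
                     crs_id = spec$crs_id)
  value_grid(cspec, out)
}
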