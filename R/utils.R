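#' Derive a reproducible per-stage seed from a global run seed
#'
#' Stages of the pipeline draw their randomness from seeds derived by
#' hashing the stage name into the global seed, so any stage can be rerun
#' in isolation and reproduce its output exactly.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in integer range
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% m
  s <- (as.numeric(seed) %% m * 48271 + h) %% m
  as.integer(max(1, s))
}

.log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Min-max scale values to [0, 1]
#'
#' Linear rescale `(x - min) / (max - min)` over the finite values. A
#' constant input cannot be ranked, so every value is mapped to 0.5 with a
#' warning.
#'
#' @param x Numeric vector (may contain `NA`).
#' @return Numeric vector in `[0, 1]`, `NA` preserved.
#' @export
minmax_scale <- function(x) {
  fin <- x[!is.na(x)]
  if (!length(fin)) return(x)
  lo <- min(fin)
  hi <- max(fin)
  if (hi == lo) {
    warning("constant input to minmax_scale; returning 0.5")
    out <- x
    out[!is.na(x)] <- 0.5
    return(out)
  }
  (x - lo) / (hi - lo)
}

# checksum of a grid's contents (used by the run report's determinism record)
.grid_checksum <- function(grid) {
  f <- tempfile(fileext = ".asc")
  on.exit(unlink(c(f, paste0(f, ".json"))), add = TRUE)
  write_raster(grid, f)
  unname(tools::md5sum(f))
}

.stopifnot_value_grid <- function(x, name = deparse(substitute(x))) {
  if (!inherits(x, "value_grid"))
    stop(sprintf("%s must be a value_grid", name))
  invisible(TRUE)
}
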