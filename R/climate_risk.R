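# Climate-risk layer: predicted change in maximum surface temperature
# between two periods and the multi-model uncertainty. Kept out of the
# hotspot scores by design — rising temperatures both threaten restoration
# longevity and strengthen the case for restoring, so the layer is
# reported separately and no scoring function accepts it.

#' Maximum-surface-temperature change and multi-model uncertainty
#'
#' Per model and cell, averages the monthly maximum-surface-temperature
#' layers within each period and differences the two period means; the
#' reported change is the across-model mean of these deltas (an absolute
#' change in degC) and the uncertainty is the standard error of that mean,
#' `sd(deltas) / sqrt(n_models)`. With a single model the delta is
#' computed but the uncertainty is undefined (nodata). The alternative
#' `monthly_abs` mode averages the absolute values of the twelve
#' month-wise climatology differences instead, for sensitivity to the
#' aggregation order.
#'
#' @param models List, one element per climate model, each a list with
#'   `initial` and `end`: lists of monthly [value_grid()]s (>= 12 layers
#'   per period; layer `i` is month `(i - 1) %% 12 + 1`).
#' @param mode `"period_mean"` (default) or `"monthly_abs"`.
#' @return A `climate_risk_result`: `delta_stmax` ([value_grid()], degC),
#'   `uncertainty` ([value_grid()], degC standard error), `n_models`.
#' @export
stmax_delta <- function(models, mode = c("period_mean", "monthly_abs")) {
  mode <- match.arg(mode)
  if (is.list(models) && !is.null(models$models)) models <- models$models
  stopifnot(length(models) >= 1L)
  spec <- models[[1]]$initial[[1]]$spec
  for (m in models) {
    if (length(m$initial) < 12L || length(m$end) < 12L)
      stop("each period needs >= 12 monthly layers per model")
    for (g in c(m$initial, m$end)) .check_aligned(models[[1]]$initial[[1]], g,
                                                  "climate layers")
  }
  period_mean <- function(layers)
    Reduce(`+`, lapply(layers, `[[`, "values")) / length(layers)
  monthly_clim <- function(layers) {
    mons <- ((seq_along(layers) - 1L) %% 12L) + 1L
    lapply(1:12, function(mo) {
      sel <- layers[mons == mo]
      Reduce(`+`, lapply(sel, `[[`, "values")) / length(sel)
    })
  }
  deltas <- lapply(models, function(m) {
    if (mode == "period_mean") {
      period_mean(m$end) - period_mean(m$initial)
    } else {
      ci <- monthly_clim(m$initial)
      ce <- monthly_clim(m$end)
      Reduce(`+`, Map(function(a, b) abs(b - a), ci, ce)) / 12
    }
  })
  n <- length(deltas)
  mean_d <- Reduce(`+`, deltas) / n
  if (n >= 2L) {
    ss <- Reduce(`+`, lapply(deltas, function(d) (d - mean_d)^2))
    se <- sqrt(ss / (n - 1)) / sqrt(n)
    unc <- value_grid(spec, se)
  } else {
    unc <- value_grid(spec, NA_real_)
  }
  structure(list(delta_stmax = value_grid(spec, mean_d), uncertainty = unc,
                 n_models = n, mode = mode),
            class = "climate_risk_result")
}

#' @export
print.climate_risk_result <- function(x, ...) {
  cat(sprintf("<climate_risk_result> %d model(s), mean delta %.2f degC\n",
              x$n_models, mean(x$delta_stmax$values, na.rm = TRUE)))
  invisible(x)
}
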