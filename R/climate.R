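#' Pair two co-registered temperature epochs
#'
#' @param tOld,tNew [GeoGrid-class] temperature layers (degrees C) with
#'   identical geometry, e.g. Last Interglacial and Last Glacial Maximum.
#' @param deltaYears years separating the epochs (default 110000, roughly
#'   LIG ~130 ka to LGM ~21 ka).
#' @return a [ClimateEpochPair-class].
#' @export
climateEpochPair <- function(tOld, tNew, deltaYears = 110000) {
  new("ClimateEpochPair", tOld = tOld, tNew = tNew,
      deltaYears = as.numeric(deltaYears))
}

setMethod("show", "ClimateEpochPair", function(object) {
  cat(sprintf("ClimateEpochPair: %d x %d cells, %.6g years apart\n",
              nrow(object@tOld@values), ncol(object@tOld@values),
              object@deltaYears))
  invisible(object)
})

#' Temporal rate of temperature change
#'
#' `|t_new - t_old| / delta_years` per cell, in degrees C per year; nodata
#' where either epoch is nodata.
#'
#' @param pair a [ClimateEpochPair-class].
#' @return a [GeoGrid-class] of rates (degrees C / yr).
#' @export
temporalRate <- function(pair) {
  g <- pair@tOld
  GeoGrid(abs(pair@tNew@values - pair@tOld@values) / pair@deltaYears,
          xOrigin = g@xOrigin, yOrigin = g@yOrigin, cellSize = g@cellSize,
          nodata = g@nodata)
}

#' Spatial temperature gradient magnitude
#'
#' Magnitude of the horizontal temperature gradient in degrees C per km via
#' the same Horn stencil as terrain slope, with metric ground distances;
#' border cells are nodata.
#'
#' @param t a [GeoGrid-class] of temperature, at least 3 x 3.
#' @return a [GeoGrid-class] of gradient magnitude (degrees C / km).
#' @export
spatialGradient <- function(t) {
  g <- hornGradient(t, "metric")
  GeoGrid(sqrt(g$p^2 + g$q^2) * 1000, xOrigin = t@xOrigin,
          yOrigin = t@yOrigin, cellSize = t@cellSize, nodata = t@nodata)
}

#' Temperature-change velocity between epochs
#'
#' The speed an organism must move to keep its temperature constant:
#' temporal rate divided by local spatial gradient, reported in km per
#' century. Cells whose gradient falls below `gFloor` (the flat-field
#' degenerate case, the classic failure mode of velocity maps) receive the
#' deterministic ceiling `vCap`; all values are clamped to `[0, vCap]`.
#'
#' @param pair a [ClimateEpochPair-class].
#' @param gradientSource `"old"` (default: gradient of the earlier epoch),
#'   `"new"`, or `"mean"` (gradient of the cell-mean temperature field).
#' @param vCap ceiling in km/century (default 10000).
#' @param gFloor gradient floor in degrees C / km (default 1e-6).
#' @return a [VelocityGrid-class] (km/century).
#' @examples
#' # 5 degC over 100 kyr across a 5 degC/km gradient -> 0.001 km/century
#' @export
climateVelocity <- function(pair, gradientSource = c("old", "new", "mean"),
                            vCap = 10000, gFloor = 1e-6) {
  gradientSource <- match.arg(gradientSource)
  if (!is.finite(vCap) || vCap <= 0)
    pcStop("pcParameterError", "vCap must be a single positive number")
  rate <- temporalRate(pair)@values           # degC / yr
  gfield <- switch(gradientSource,
                   old = pair@tOld,
                   new = pair@tNew,
                   mean = {
                     g <- pair@tOld
                     GeoGrid((pair@tOld@values + pair@tNew@values) / 2,
                             xOrigin = g@xOrigin, yOrigin = g@yOrigin,
                             cellSize = g@cellSize, nodata = g@nodata)
                   })
  grad <- spatialGradient(gfield)@values      # degC / km
  v <- rate / grad * 100                      # km / yr -> km / century
  flat <- !is.na(grad) & grad < gFloor & !is.na(rate)
  v[flat] <- vCap
  v[!is.na(v) & v > vCap] <- vCap
  g <- pair@tOld
  new("VelocityGrid",
      GeoGrid(v, xOrigin = g@xOrigin, yOrigin = g@yOrigin,
              cellSize = g@cellSize, nodata = g@nodata),
      vCap = as.numeric(vCap))
}

#' Climatic stability mask (refugium nomination)
#'
#' Areas of low temperature-change velocity remained climatically stable and
#' are nominated as refugia. Open (stable) cells are those with velocity at
#' or below the empirical `quantile` of the finite velocities; the threshold
#' is the rank statistic `round(quantile * n)` and the comparison is
#' inclusive, so ties are stable rather than arbitrary. Mask semantics:
#' blocked (1) means "not a refugium".
#'
#' @param v a [VelocityGrid-class].
#' @param quantile fraction in (0, 1) of cells to keep as stable.
#' @return a [Mask-class]; open (0) cells are the refugia.
#' @export
stabilityMask <- function(v, quantile = 0.25) {
  if (quantile <= 0 || quantile >= 1)
    pcStop("pcParameterError", "quantile must lie strictly in (0, 1)")
  vals <- v@values
  fin <- vals[!is.na(vals)]
  if (!length(fin))
    pcStop("pcEmptyInputError", "velocity grid has no data cells")
  k <- min(max(1L, as.integer(floor(quantile * length(fin) + 0.5))), length(fin))
  thr <- sort(fin, partial = k)[k]
  stable <- !is.na(vals) & vals <= thr
  newMask(v, !stable)
}

setMethod("show", "VelocityGrid", function(object) {
  callNextMethod()
  cat(sprintf("  velocity ceiling vCap = %.6g km/century\n", object@vCap))
  invisible(object)
})
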