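#' Build a movement-cost surface from slope and barriers
#'
#' Higher slope means higher movement cost. The default linear form is
#' `cost = 1 + kSlope * slope_degrees` at open cells (the minimal monotone
#' assumption: with the default `kSlope = 0.1`, cost doubles at 10 degrees).
#' The Tobler alternative derives cost from the hiking function as the
#' reciprocal of relative walking speed, `cost = exp(3.5 * tan(slope))`
#' normalised to 1 on flat ground. Blocked and nodata cells become `Inf`
#' (non-traversable).
#'
#' @param slope [GeoGrid-class] of slope in degrees (see [computeSlope()]).
#' @param blocked [Mask-class] of barrier cells, same geometry.
#' @param kSlope cost per degree of slope, >= 0 (linear form only).
#' @param costFunction `"linear"` (default) or `"tobler"`.
#' @param softBarrier optional [Mask-class] whose blocked cells get a finite
#'   `softMultiplier` instead of `Inf` (desert sensitivity analyses).
#' @param softMultiplier finite multiplier >= 1 for `softBarrier` cells.
#' @param scenarioName provenance label.
#' @return a [CostSurface-class].
#' @export
buildCostSurface <- function(slope, blocked, kSlope = 0.1,
                             costFunction = c("linear", "tobler"),
                             softBarrier = NULL, softMultiplier = 1,
                             scenarioName = NA_character_) {
  costFunction <- match.arg(costFunction)
  checkSameGeometry(slope, blocked, "slope grid and mask")
  if (!is.finite(kSlope) || kSlope < 0)
    pcStop("pcParameterError", "kSlope must be a finite non-negative number")
  s <- slope@values
  cost <- switch(costFunction,
                 linear = 1 + kSlope * s,
                 tobler = exp(3.5 * tan(pmin(s, 89.9) * pi / 180)))
  if (!is.null(softBarrier)) {
    checkSameGeometry(slope, softBarrier, "slope grid and soft barrier")
    if (!is.finite(softMultiplier) || softMultiplier < 1)
      pcStop("pcParameterError", "softMultiplier must be finite and >= 1")
    soft <- blockedCells(softBarrier)
    cost[soft] <- cost[soft] * softMultiplier
  }
  cost[is.na(s) | blockedCells(blocked)] <- Inf
  new("CostSurface",
      GeoGrid(cost, xOrigin = slope@xOrigin, yOrigin = slope@yOrigin,
              cellSize = slope@cellSize, nodata = slope@nodata),
      provenance = list(scenario = scenarioName, kSlope = kSlope,
                        costFunction = costFunction))
}

setMethod("show", "CostSurface", function(object) {
  v <- object@values
  cat(sprintf("CostSurface: %d x %d cells, %d blocked, finite cost %.4g-%.4g (scenario: %s)\n",
              nrow(v), ncol(v), sum(!is.finite(v)),
              min(v[is.finite(v)]), max(v[is.finite(v)]),
              object@provenance$scenario))
  invisible(object)
})

#' Least-cost path between two points
#'
#' Dijkstra's algorithm over the 8-connected cell lattice. The edge weight
#' between neighboring cells i and j is `d(i, j) * (cost_i + cost_j) / 2`,
#' where `d` is the great-circle distance between cell centers in km
#' (trapezoidal transition rule). Ties between equal-cost paths are broken
#' toward the lexicographically smallest predecessor (row, then column), so
#' outputs are byte-reproducible. Endpoints snap to their containing cell
#' center; a blocked endpoint cell fails loudly rather than snapping to the
#' nearest open cell, which could silently jump a barrier.
#'
#' @param cost a [CostSurface-class].
#' @param start,end (lon, lat) vectors of the endpoints.
#' @param distance `"greatcircle"` (default) or `"unit"` (planar lattice
#'   with unit-km cells, for analytic tests).
#' @param startName,endName,scenarioName labels carried into the result.
#' @return a [DispersalPath-class].
#' @section Errors:
#' `pcPlacementError` when an endpoint is off-grid or on a blocked cell;
#' `pcUnreachableError` when every route is severed by barriers (the
#' populations-lost-connection regime).
#' @export
leastCostPath <- function(cost, start, end,
                          distance = c("greatcircle", "unit"),
                          startName = "start", endName = "end",
                          scenarioName = NA_character_) {
  distance <- match.arg(distance)
  s <- cellIndexAt(cost, start[1], start[2])
  e <- cellIndexAt(cost, end[1], end[2])
  v <- cost@values
  for (pt in list(c(s, "start"), c(e, "end"))) {
    r <- as.integer(pt[1]); cc <- as.integer(pt[2])
    if (!is.finite(v[r, cc]))
      pcStop("pcPlacementError",
             sprintf("%s point falls on blocked cell (%d, %d)", pt[3], r, cc))
  }
  res <- lcp_dijkstra(v, s[1] - 1L, s[2] - 1L, e[1] - 1L, e[2] - 1L,
                      cost@xOrigin, cost@yOrigin, cost@cellSize,
                      distance == "unit")
  if (!is.finite(res$totalCost))
    pcStop("pcUnreachableError",
           sprintf("no finite-cost route from %s to %s: endpoints are severed by barriers",
                   startName, endName))
  cells <- cbind(res$rows + 1L, res$cols + 1L)
  coords <- cellCenters(cost, rows = cells[, 1], cols = cells[, 2])
  lengthKm <- if (nrow(coords) < 2L) 0 else
    sum(haversineKm(coords[-nrow(coords), 1], coords[-nrow(coords), 2],
                    coords[-1, 1], coords[-1, 2]))
  new("DispersalPath", cells = cells, coords = coords,
      totalCost = res$totalCost, lengthKm = lengthKm,
      scenario = scenarioName, start = startName, end = endName,
      distanceMode = distance)
}

setMethod("show", "DispersalPath", function(object) {
  cat(sprintf("DispersalPath %s -> %s (%s): %d cells, total cost %.4g, length %.1f km\n",
              object@start, object@end,
              ifelse(is.na(object@scenario), "no scenario", object@scenario),
              nrow(object@cells), object@totalCost, object@lengthKm))
  invisible(object)
})

#' Geodesic length of a dispersal path
#'
#' Sum of great-circle segment lengths between consecutive cell centers
#' (mean Earth radius); zero for paths with fewer than two cells.
#'
#' @param path a [DispersalPath-class] or an n x 2 (lon, lat) matrix.
#' @return length in km.
#' @export
pathLengthKm <- function(path) {
  coords <- if (is(path, "DispersalPath")) path@coords else as.matrix(path)
  n <- nrow(coords)
  if (n < 2L) return(0)
  sum(haversineKm(coords[-n, 1], coords[-n, 2], coords[-1, 1], coords[-1, 2]))
}

#' Write / read a dispersal path as GeoJSON
#'
#' The path is stored as a `LineString` feature with `total_cost`,
#' `length_km`, `scenario`, `start` and `end` properties.
#'
#' @param path a [DispersalPath-class].
#' @param file destination / source file.
#' @return `writePathGeoJSON` returns `file` invisibly; `readPathGeoJSON`
#'   returns a list with `coords` (matrix) and `properties` (list).
#' @export
writePathGeoJSON <- function(path, file) {
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = unname(apply(path@coords, 1L, function(p)
                        c(p[[1]], p[[2]]), simplify = FALSE))),
      properties = list(total_cost = path@totalCost,
                        length_km = path@lengthKm,
                        scenario = path@scenario,
                        start = path@start, end = path@end)
    ))
  )
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname writePathGeoJSON
#' @export
readPathGeoJSON <- function(file) {
  gj <- jsonlite::read_json(file)
  feat <- gj$features[[1]]
  coords <- do.call(rbind, lapply(feat$geometry$coordinates, unlist))
  colnames(coords) <- c("lon", "lat")
  list(coords = coords, properties = feat$properties)
}
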