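#' GeoGrid: a georeferenced north-up raster
#'
#' The universal carrier of gridded values in the package (elevation in m asl,
#' slope in degrees, cost multipliers, temperature in degrees C, velocity in
#' km/century). Cell (1,1) is the north-west corner; row index increases
#' southward and column index eastward. `xOrigin`/`yOrigin` give the outer
#' (north-west) corner of cell (1,1) in decimal degrees and `cellSize` the
#' square cell edge in decimal degrees. Nodata cells are held as `NA_real_`
#' in memory; the `nodata` slot records only the on-disk sentinel used when
#' writing. Only the geographic WGS84 dialect (`crsTag =
#' "geographic-WGS84"`) is supported.
#'
#' @slot values numeric matrix of cell values (`NA` = nodata).
#' @slot xOrigin,yOrigin numeric, NW corner of cell (1,1), decimal degrees.
#' @slot cellSize numeric, positive cell edge in decimal degrees.
#' @slot nodata numeric, sentinel written to disk for `NA` cells.
#' @slot crsTag character, coordinate dialect tag.
#'
#' @seealso [GeoGrid()], [readGrid()], [writeGrid()], [alignTo()]
#' @exportClass GeoGrid
setClass("GeoGrid", representation(
  values = "matrix",
  xOrigin = "numeric",
  yOrigin = "numeric",
  cellSize = "numeric",
  nodata = "numeric",
  crsTag = "character"
))

setValidity("GeoGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (length(dim(v)) != 2L || nrow(v) < 1L || ncol(v) < 1L)
    return("values must be a non-empty 2-D matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    return("cellSize must be a single positive number")
  if (length(object@xOrigin) != 1L || length(object@yOrigin) != 1L ||
      !is.finite(object@xOrigin) || !is.finite(object@yOrigin))
    return("xOrigin/yOrigin must be single finite numbers")
  if (!identical(object@crsTag, "geographic-WGS84"))
    return("only the 'geographic-WGS84' dialect is supported")
  TRUE
})

#' Mask: a boolean barrier raster
#'
#' A [GeoGrid] whose values are 0 (open) or 1 (blocked). Masks are the
#' composable representation of barriers: flooded sea, desert polygons,
#' elevation suitability bands. They carry no nodata cells: every cell is
#' decided.
#'
#' @seealso [floodFillSea()], [elevationBandMask()], [polygonMask()],
#'   [combineMasks()]
#' @exportClass Mask
setClass("Mask", contains = "GeoGrid")

setValidity("Mask", function(object) {
  v <- object@values
  if (anyNA(v)) return("Mask cells must be decided (no NA)")
  if (!all(v == 0 | v == 1)) return("Mask values must be 0 (open) or 1 (blocked)")
  TRUE
})

#' BarrierScenario: one paleo-stage barrier hypothesis
#'
#' Bundles the Caspian-style sea stand, the elevation suitability band and
#' desert barrier polygons into a named scenario, e.g. the MIS 4 Atelian
#' regression at -140 m asl.
#'
#' @slot name scenario label, e.g. `"MIS4-Atelian"`.
#' @slot seaLevel sea stand in m asl (paper stands: present -27, Late
#'   Khazarian -10, Atelian -120 to -140, Early Khvalynian +50).
#' @slot seaSeed numeric length 2, (lon, lat) of a point inside the basin.
#' @slot minSuitableElev,maxSuitableElev m asl bounds of the suitability band
#'   (default 50 and 1800; the band is the closed interval, boundary open).
#' @slot barrierPolygons list of polygon rings (matrices with columns
#'   lon, lat) treated as impassable deserts.
#' @slot applyBand logical; apply the suitability band to routing (off by
#'   default: the band defines the corridor habitat zone, not a universal
#'   routing constraint).
#' @slot desertCostMultiplier finite multiplier for sensitivity analyses;
#'   `Inf` (default) makes deserts absolute barriers.
#'
#' @seealso [barrierScenario()], [caspianStands()], [scenarioMask()]
#' @exportClass BarrierScenario
setClass("BarrierScenario", representation(
  name = "character",
  seaLevel = "numeric",
  seaSeed = "numeric",
  minSuitableElev = "numeric",
  maxSuitableElev = "numeric",
  barrierPolygons = "list",
  applyBand = "logical",
  desertCostMultiplier = "numeric"
))

setValidity("BarrierScenario", function(object) {
  if (length(object@seaSeed) != 2L) return("seaSeed must be (lon, lat)")
  if (object@minSuitableElev >= object@maxSuitableElev)
    return("minSuitableElev must be below maxSuitableElev")
  if (object@desertCostMultiplier < 1)
    return("desertCostMultiplier must be >= 1 (or Inf for a hard barrier)")
  TRUE
})

#' CostSurface: per-cell traversal cost
#'
#' A [GeoGrid] of dimensionless cost multipliers (>= 1) with `Inf` marking
#' non-traversable cells (barriers and DEM nodata). The `provenance` list
#' records the scenario name and cost parameters that produced it.
#'
#' @slot provenance list with elements such as `scenario`, `kSlope`,
#'   `costFunction`.
#' @seealso [buildCostSurface()], [leastCostPath()]
#' @exportClass CostSurface
setClass("CostSurface", contains = "GeoGrid",
         representation(provenance = "list"))

setValidity("CostSurface", function(object) {
  v <- object@values
  if (anyNA(v)) return("CostSurface encodes blocked cells as Inf, not NA")
  if (any(v[is.finite(v)] < 1)) return("finite costs must be >= 1")
  TRUE
})

#' DispersalPath: a least-cost route between two sites
#'
#' Ordered cell indices and cell-center coordinates of a route on the cost
#' lattice, with its accumulated cost (cost x km) and geodesic length (km).
#'
#' @slot cells integer matrix (n x 2) of (row, col), 1-based.
#' @slot coords numeric matrix (n x 2) of (lon, lat) cell centers.
#' @slot totalCost accumulated cost in cost-km.
#' @slot lengthKm great-circle length of the polyline in km.
#' @slot scenario,start,end labels carried for reporting.
#' @slot distanceMode `"greatcircle"` or `"unit"` (planar unit-km cells,
#'   used for small analytic tests).
#' @seealso [leastCostPath()], [pathLengthKm()], [bufferCorridor()]
#' @exportClass DispersalPath
setClass("DispersalPath", representation(
  cells = "matrix",
  coords = "matrix",
  totalCost = "numeric",
  lengthKm = "numeric",
  scenario = "character",
  start = "character",
  end = "character",
  distanceMode = "character"
))

setValidity("DispersalPath", function(object) {
  cl <- object@cells
  if (ncol(cl) != 2L) return("cells must be an n x 2 (row, col) matrix")
  if (nrow(cl) != nrow(object@coords)) return("cells and coords disagree")
  if (nrow(cl) > 1L) {
    dr <- abs(diff(cl[, 1L])); dc <- abs(diff(cl[, 2L]))
    if (any(pmax(dr, dc) != 1L))
      return("consecutive path cells must be 8-neighbors")
  }
  if (object@totalCost < 0) return("totalCost must be non-negative")
  TRUE
})

#' Corridor: settlement-potential buffer around a dispersal path
#'
#' Membership is by minimum great-circle distance from a query point to the
#' path polyline (segments, not just vertices), compared against `bufferKm`.
#'
#' @slot coords numeric matrix (n x 2) of path vertex (lon, lat).
#' @slot bufferKm buffer radius in km (default 30, the settlement-potential
#'   buffer half-width).
#' @slot source label of the originating path.
#' @seealso [bufferCorridor()], [sitesInCorridor()], [inCorridor()]
#' @exportClass Corridor
setClass("Corridor", representation(
  coords = "matrix",
  bufferKm = "numeric",
  source = "character"
))

setValidity("Corridor", function(object) {
  if (nrow(object@coords) < 1L) return("corridor needs at least one vertex")
  if (length(object@bufferKm) != 1L || object@bufferKm <= 0)
    return("bufferKm must be a single positive number")
  TRUE
})

#' ClimateEpochPair: two co-registered temperature epochs
#'
#' Temperature grids for an older and a newer epoch (degrees C) plus the
#' years separating them, e.g. Last Interglacial to Last Glacial Maximum.
#'
#' @slot tOld,tNew [GeoGrid] of temperature, identical geometry.
#' @slot deltaYears positive number of years between the epochs.
#' @seealso [climateEpochPair()], [temporalRate()], [climateVelocity()]
#' @exportClass ClimateEpochPair
setClass("ClimateEpochPair", representation(
  tOld = "GeoGrid",
  tNew = "GeoGrid",
  deltaYears = "numeric"
))

setValidity("ClimateEpochPair", function(object) {
  if (!sameGeometry(object@tOld, object@tNew))
    return("tOld and tNew must share geometry")
  if (length(object@deltaYears) != 1L || object@deltaYears <= 0)
    return("deltaYears must be a single positive number")
  TRUE
})

#' VelocityGrid: climate-change velocity map
#'
#' A [GeoGrid] of temperature-change velocity in km per century, with all
#' finite values in `[0, vCap]`; `vCap` is the deterministic ceiling applied
#' where the spatial temperature gradient vanishes.
#'
#' @slot vCap ceiling in km/century.
#' @seealso [climateVelocity()], [stabilityMask()]
#' @exportClass VelocityGrid
setClass("VelocityGrid", contains = "GeoGrid",
         representation(vCap = "numeric"))

setValidity("VelocityGrid", function(object) {
  v <- object@values
  fin <- v[!is.na(v)]
  if (length(fin) && (any(fin < 0) || any(fin > object@vCap + 1e-12)))
    return("velocities must lie in [0, vCap]")
  TRUE
})
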