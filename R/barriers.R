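#' Construct a barrier scenario
#'
#' A named bundle of one paleo-stage barrier hypothesis: the sea stand of the
#' closed basin, the elevation suitability band, and desert polygons. See
#' [caspianStands()] for the published stands.
#'
#' @param name scenario label.
#' @param seaLevel sea stand in m asl.
#' @param seaSeed (lon, lat) of a point inside the sea basin.
#' @param minSuitableElev,maxSuitableElev suitability band bounds in m asl
#'   (defaults 50 and 1800); the band is the closed interval, so boundary
#'   cells are open.
#' @param barrierPolygons list of polygon rings (n x 2 lon/lat matrices)
#'   treated as impassable deserts.
#' @param applyBand apply the band as a routing constraint (default `FALSE`;
#'   the band delimits the corridor habitat zone, while continental routes
#'   legitimately cross plains below 50 m).
#' @param desertCostMultiplier `Inf` (default) for hard barriers; a finite
#'   multiplier >= 1 for sensitivity analyses.
#' @return a [BarrierScenario-class].
#' @export
barrierScenario <- function(name, seaLevel, seaSeed,
                            minSuitableElev = 50, maxSuitableElev = 1800,
                            barrierPolygons = list(), applyBand = FALSE,
                            desertCostMultiplier = Inf) {
  new("BarrierScenario", name = name, seaLevel = as.numeric(seaLevel),
      seaSeed = as.numeric(seaSeed), minSuitableElev = as.numeric(minSuitableElev),
      maxSuitableElev = as.numeric(maxSuitableElev),
      barrierPolygons = barrierPolygons, applyBand = applyBand,
      desertCostMultiplier = as.numeric(desertCostMultiplier))
}

setMethod("show", "BarrierScenario", function(object) {
  cat(sprintf("BarrierScenario '%s': sea %.6g m asl, band [%.6g, %.6g] m (%s), %d desert polygon(s)\n",
              object@name, object@seaLevel, object@minSuitableElev,
              object@maxSuitableElev,
              if (object@applyBand) "applied" else "reporting only",
              length(object@barrierPolygons)))
  invisible(object)
})

#' Published Caspian sea-level stands
#'
#' Named presets in m asl: present (-27), the Late Khazarian highstand
#' (-10, MIS 5), both published endpoints of the Atelian lowstand
#' (-120/-140, MIS 4) and the Early Khvalynian highstand (+50, late MIS 3).
#'
#' @return named numeric vector of sea levels in m asl.
#' @export
caspianStands <- function() {
  c(atelian_low = -140, atelian_high = -120, present = -27,
    late_khazarian = -10, early_khvalynian = 50)
}

#' @noRd
newMask <- function(template, blocked) {
  m <- matrix(0, nrow(template@values), ncol(template@values))
  m[blocked] <- 1
  new("Mask", GeoGrid(m, xOrigin = template@xOrigin,
                      yOrigin = template@yOrigin,
                      cellSize = template@cellSize,
                      nodata = template@nodata))
}

#' Blocked-cell matrix of a mask
#'
#' @param mask a [Mask-class].
#' @return logical matrix, `TRUE` where blocked.
#' @export
blockedCells <- function(mask) mask@values == 1

#' Flood-fill a closed sea basin
#'
#' Blocked cells are those with elevation at or below `seaLevel` that are
#' 4-connected to the seed cell. Because the basin is closed, inundation is
#' connectivity-limited: depressions below the stand that do not connect to
#' the seed stay dry. 4-connectivity prevents the sea "leaking" diagonally
#' through one-cell land bridges that 8-connected routing could not cross
#' anyway. Nodata cells never flood.
#'
#' @param dem [GeoGrid-class] of elevation.
#' @param seaLevel stand in m asl.
#' @param seaSeed (lon, lat) inside the basin.
#' @return a [Mask-class]; empty (plus a `pcDrySeedWarning`) when the seed
#'   cell lies above the stand.
#' @export
floodFillSea <- function(dem, seaLevel, seaSeed) {
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  seed <- cellIndexAt(dem, seaSeed[1], seaSeed[2])
  wet <- !is.na(z) & z <= seaLevel
  if (!wet[seed[1], seed[2]]) {
    pcWarn("pcDrySeedWarning",
           sprintf("seed cell (%d, %d) is above the %.6g m stand: empty sea",
                   seed[1], seed[2], seaLevel))
    return(newMask(dem, matrix(FALSE, nr, nc)))
  }
  visited <- matrix(FALSE, nr, nc)
  visited[seed[1], seed[2]] <- TRUE
  frontier <- (seed[2] - 1L) * nr + seed[1] # column-major linear index
  while (length(frontier)) {
    r <- (frontier - 1L) %% nr + 1L
    cl <- (frontier - 1L) %/% nr + 1L
    nb <- c(frontier[r > 1L] - 1L, frontier[r < nr] + 1L,
            frontier[cl > 1L] - nr, frontier[cl < nc] + nr)
    nb <- unique(nb[wet[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  newMask(dem, visited)
}

#' Elevation suitability band mask
#'
#' Blocks cells strictly below `minElev` or strictly above `maxElev`; the
#' band is a closed interval, so boundary cells stay open ("less than 50 m"
#' unsuitable, "up until 1800 m" suitable). Nodata cells are blocked: their
#' suitability cannot be asserted.
#'
#' @param dem [GeoGrid-class] of elevation.
#' @param minElev,maxElev band bounds in m asl, `minElev < maxElev`.
#' @return a [Mask-class].
#' @export
elevationBandMask <- function(dem, minElev = 50, maxElev = 1800) {
  if (minElev >= maxElev)
    pcStop("pcParameterError", "minElev must be strictly below maxElev")
  z <- dem@values
  newMask(dem, is.na(z) | z < minElev | z > maxElev)
}

#' Rasterise barrier polygons to a mask
#'
#' A cell is blocked when its center lies inside any polygon under the
#' even-odd rule. Polygons are closed automatically. Rings may overlap; a
#' point inside an even number of rings of the *same* polygon list entry is
#' outside (holes work naturally), while separate list entries are OR-ed.
#'
#' @param reference [GeoGrid-class] providing the geometry.
#' @param polygons list; each element is either an n x 2 (lon, lat) matrix
#'   (one ring) or a list of such rings belonging to one polygon.
#' @return a [Mask-class].
#' @export
polygonMask <- function(reference, polygons) {
  nr <- nrow(reference@values); nc <- ncol(reference@values)
  ctr <- cellCenters(reference)
  px <- matrix(ctr$lon, nr, nc, byrow = TRUE)
  py <- matrix(ctr$lat, nr, nc)
  blocked <- matrix(FALSE, nr, nc)
  for (poly in polygons) {
    rings <- if (is.list(poly)) poly else list(poly)
    crossings <- matrix(0L, nr, nc)
    for (ring in rings) {
      ring <- closeRing(as.matrix(ring))
      checkSimpleRing(ring)
      n <- nrow(ring) - 1L
      for (i in seq_len(n)) {
        x1 <- ring[i, 1]; y1 <- ring[i, 2]
        x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
        if (y1 == y2) next
        straddles <- (py > pmin(y1, y2)) & (py <= pmax(y1, y2))
        xInt <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
        crossings <- crossings + (straddles & (px < xInt))
      }
    }
    blocked <- blocked | (crossings %% 2L == 1L)
  }
  newMask(reference, blocked)
}

#' @noRd
closeRing <- function(ring) {
  if (nrow(ring) < 3L)
    pcStop("pcGeometryError", "polygon ring needs at least 3 vertices")
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

# Reject self-intersecting rings (non-adjacent proper segment crossings).
#' @noRd
checkSimpleRing <- function(ring) {
  n <- nrow(ring) - 1L
  seg <- function(i) list(a = ring[i, ], b = ring[i + 1L, ])
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next # first and last share the closing vertex
      s1 <- seg(i); s2 <- seg(j)
      d1 <- crossSign(s2$a, s2$b, s1$a); d2 <- crossSign(s2$a, s2$b, s1$b)
      d3 <- crossSign(s1$a, s1$b, s2$a); d4 <- crossSign(s1$a, s1$b, s2$b)
      if (d1 * d2 < 0 && d3 * d4 < 0)
        pcStop("pcGeometryError", "self-intersecting polygon ring")
    }
  }
  invisible(TRUE)
}

#' @noRd
crossSign <- function(a, b, p)
  sign((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]))

#' Combine masks by logical OR
#'
#' A cell is blocked when blocked in any input; commutative, associative and
#' idempotent.
#'
#' @param masks list of [Mask-class] objects with identical geometry (a bare
#'   `Mask` is accepted).
#' @return a [Mask-class].
#' @export
combineMasks <- function(masks) {
  if (is(masks, "Mask")) masks <- list(masks)
  if (!length(masks)) pcStop("pcParameterError", "no masks to combine")
  out <- blockedCells(masks[[1]])
  for (m in masks[-1]) {
    checkSameGeometry(masks[[1]], m, "masks")
    out <- out | blockedCells(m)
  }
  newMask(masks[[1]], out)
}

#' Composite routing mask of a scenario
#'
#' Floods the sea at the scenario's stand, rasterises the desert polygons
#' and, when `applyBand` is set (or `applyBand = TRUE` is forced here),
#' adds the elevation suitability band.
#'
#' @param dem [GeoGrid-class] of elevation.
#' @param scenario a [BarrierScenario-class].
#' @param applyBand override the scenario's `applyBand` flag.
#' @param includeDeserts set `FALSE` to drop the desert polygons (used for
#'   sensitivity analysis of the desert barrier).
#' @return a [Mask-class] of non-traversable cells.
#' @export
scenarioMask <- function(dem, scenario, applyBand = scenario@applyBand,
                         includeDeserts = TRUE) {
  masks <- list(floodFillSea(dem, scenario@seaLevel, scenario@seaSeed))
  if (includeDeserts && length(scenario@barrierPolygons) &&
      !is.finite(scenario@desertCostMultiplier))
    masks <- c(masks, list(polygonMask(dem, scenario@barrierPolygons)))
  if (applyBand)
    masks <- c(masks, list(elevationBandMask(dem, scenario@minSuitableElev,
                                             scenario@maxSuitableElev)))
  combineMasks(masks)
}

#' The corridor strip: habitat band between the sea and the high mountains
#'
#' Operationalises the narrow coastal corridor (the Southern Caspian
#' Corridor analog): cells that are not flooded at the scenario's stand, not
#' desert, no higher than the scenario's `maxSuitableElev` (the 1800 m
#' contour), and not north of the sea (a cell is "north of the sea" when
#' flooded cells exist further south in its own column). Open cells of the
#' returned mask form the strip.
#'
#' @param dem [GeoGrid-class] of elevation.
#' @param scenario a [BarrierScenario-class].
#' @param seaLevel stand used for the bounding sea mask (defaults to the
#'   scenario's own stand).
#' @return a [Mask-class]; open (0) cells belong to the strip.
#' @export
corridorStripMask <- function(dem, scenario, seaLevel = scenario@seaLevel) {
  sea <- blockedCells(floodFillSea(dem, seaLevel, scenario@seaSeed))
  desert <- if (length(scenario@barrierPolygons))
    blockedCells(polygonMask(dem, scenario@barrierPolygons))
  else matrix(FALSE, nrow(sea), ncol(sea))
  z <- dem@values
  nr <- nrow(z)
  northOfSea <- matrix(FALSE, nr, ncol(z))
  for (cl in seq_len(ncol(z))) {
    wetRows <- which(sea[, cl])
    if (length(wetRows)) # rows above (north of) the topmost sea cell
      northOfSea[seq_len(wetRows[1] - 1L), cl] <- TRUE
  }
  blocked <- sea | desert | is.na(z) | z > scenario@maxSuitableElev | northOfSea
  newMask(dem, blocked)
}
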