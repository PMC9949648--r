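# Horn's (1981) third-order finite difference on the 3x3 neighborhood is the
# stencil behind both terrain slope and the spatial temperature gradient.

#' @noRd
shiftMat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
  out[okR, okC] <- m[rs[okR], cs[okC]]
  out
}

# Horn gradient components per meter (or per cell edge in unit mode).
# Returns list(p, q): p = dz/dx (eastward), q = dz/dy (northward magnitude
# convention is irrelevant downstream; only p^2 + q^2 is used). Border cells
# and cells with any nodata stencil neighbor are NA.
#' @noRd
hornGradient <- function(grid, groundDistance = c("metric", "unit-cell")) {
  groundDistance <- match.arg(groundDistance)
  z <- grid@values
  if (nrow(z) < 3L || ncol(z) < 3L)
    pcStop("pcSizeError", "grid must be at least 3 x 3 for the Horn stencil")
  nW <- shiftMat(z, -1, -1); nN <- shiftMat(z, -1, 0); nNE <- shiftMat(z, -1, 1)
  w  <- shiftMat(z, 0, -1);                             e  <- shiftMat(z, 0, 1)
  sW <- shiftMat(z, 1, -1);  s  <- shiftMat(z, 1, 0);  sE <- shiftMat(z, 1, 1)
  if (groundDistance == "metric") {
    dy <- grid@cellSize * .M_PER_DEG
    lat <- cellCenters(grid)$lat
    dx <- matrix(dy * cos(lat * pi / 180), nrow(z), ncol(z))
  } else {
    dy <- 1
    dx <- matrix(1, nrow(z), ncol(z))
  }
  p <- ((nNE + 2 * e + sE) - (nW + 2 * w + sW)) / (8 * dx)
  q <- ((sW + 2 * s + sE) - (nW + 2 * nN + nNE)) / (8 * dy)
  # interior cells with any nodata neighbor (or nodata center) are NA
  bad <- is.na(z) | is.na(p) | is.na(q)
  p[bad] <- NA_real_; q[bad] <- NA_real_
  list(p = p, q = q)
}

#' Terrain slope from a DEM (Horn's method)
#'
#' Slope in degrees from horizontal at each interior cell, from Horn's
#' 8-neighbor third-order finite difference: `slope = atan(sqrt(p^2 + q^2))`
#' with `p = dz/dx`, `q = dz/dy`. With `groundDistance = "metric"` the cell
#' edge is converted to meters as `dy = cellSize * 111320` and
#' `dx = dy * cos(latitude)` using each cell's own latitude, so east-west
#' distances shrink toward the poles as they do on a geographic grid. With
#' `"unit-cell"` both spacings are 1, i.e. elevations are interpreted per
#' cell edge (used for analytic tests and projected data). Border cells and
#' cells with a nodata stencil neighbor are nodata: routing should not
#' exploit artificially flat borders.
#'
#' @param dem a [GeoGrid-class] of elevation (m asl), at least 3 x 3.
#' @param groundDistance `"metric"` (default) or `"unit-cell"`.
#' @return a [GeoGrid-class] of slope in degrees, in `[0, 90)`.
#' @examples
#' dem <- GeoGrid(matrix(rep(c(10, 11, 12), 3), 3, byrow = TRUE))
#' gridValues(computeSlope(dem, "unit-cell"))[2, 2] # 45 degrees
#' @export
computeSlope <- function(dem, groundDistance = c("metric", "unit-cell")) {
  g <- hornGradient(dem, groundDistance)
  slope <- atan(sqrt(g$p^2 + g$q^2)) * 180 / pi
  GeoGrid(slope, xOrigin = dem@xOrigin, yOrigin = dem@yOrigin,
          cellSize = dem@cellSize, nodata = dem@nodata)
}
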