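#' Construct a GeoGrid
#'
#' @param values numeric matrix; `NA` marks nodata cells.
#' @param xOrigin,yOrigin north-west corner of cell (1,1), decimal degrees.
#' @param cellSize positive cell edge in decimal degrees (square cells).
#' @param nodata sentinel written for `NA` cells on export (default -9999).
#' @return a [GeoGrid-class] object.
#' @examples
#' g <- GeoGrid(matrix(1:12, 3, 4), xOrigin = 40, yOrigin = 50, cellSize = 0.5)
#' dim(g)
#' @export
GeoGrid <- function(values, xOrigin = 0, yOrigin = 0, cellSize = 1,
                    nodata = -9999) {
  storage.mode(values) <- "double"
  new("GeoGrid", values = values, xOrigin = as.numeric(xOrigin),
      yOrigin = as.numeric(yOrigin), cellSize = as.numeric(cellSize),
      nodata = as.numeric(nodata), crsTag = "geographic-WGS84")
}

#' @describeIn GeoGrid dimensions (rows, cols) of the raster.
#' @param x a `GeoGrid`.
#' @export
setMethod("dim", "GeoGrid", function(x) dim(x@values))

#' Accessors for GeoGrid geometry and values
#'
#' `gridValues` returns the value matrix (`NA` = nodata); `cellSize` the cell
#' edge in decimal degrees; `gridOrigin` the (x, y) north-west corner;
#' `nodataValue` the on-disk sentinel.
#'
#' @param x a [GeoGrid-class].
#' @return see individual descriptions.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname grid-accessors
#' @export
setMethod("gridValues", "GeoGrid", function(x) x@values)

#' @rdname grid-accessors
#' @param value replacement matrix of identical shape.
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))
#' @rdname grid-accessors
#' @export
setMethod("gridValues<-", "GeoGrid", function(x, value) {
  if (!identical(dim(value), dim(x@values)))
    pcStop("pcAlignmentError", "replacement values must keep the grid shape")
  storage.mode(value) <- "double"
  x@values <- value
  validObject(x)
  x
})

#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname grid-accessors
#' @export
setMethod("cellSize", "GeoGrid", function(x) x@cellSize)

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname grid-accessors
#' @export
setMethod("gridOrigin", "GeoGrid",
          function(x) c(x = x@xOrigin, y = x@yOrigin))

#' @rdname grid-accessors
#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))
#' @rdname grid-accessors
#' @export
setMethod("nodataValue", "GeoGrid", function(x) x@nodata)

setMethod("show", "GeoGrid", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells of %.6g deg, NW corner (%.6g, %.6g)\n",
              class(object), nrow(v), ncol(v), object@cellSize,
              object@xOrigin, object@yOrigin))
  fin <- v[!is.na(v)]
  if (length(fin))
    cat(sprintf("  values: min %.4g / mean %.4g / max %.4g, %d nodata cell(s)\n",
                min(fin[is.finite(fin)], Inf), mean(fin[is.finite(fin)]),
                max(fin[is.finite(fin)], -Inf), sum(is.na(v))))
  else cat("  all cells nodata\n")
  invisible(object)
})

#' Longitude/latitude of cell centers
#'
#' Cell centers follow the north-up convention: center of cell (r, c) is
#' `(xOrigin + (c - 0.5) * cellSize, yOrigin - (r - 0.5) * cellSize)`.
#'
#' @param grid a [GeoGrid-class].
#' @param rows,cols optional integer vectors of cell indices (recycled
#'   pairwise); by default the full vectors of row/col center coordinates
#'   are returned as a list.
#' @return if `rows` is given, an n x 2 matrix of (lon, lat); otherwise a
#'   list with components `lon` (length ncol) and `lat` (length nrow).
#' @export
cellCenters <- function(grid, rows = NULL, cols = NULL) {
  cs <- grid@cellSize
  if (is.null(rows)) {
    list(lon = grid@xOrigin + (seq_len(ncol(grid@values)) - 0.5) * cs,
         lat = grid@yOrigin - (seq_len(nrow(grid@values)) - 0.5) * cs)
  } else {
    cbind(lon = grid@xOrigin + (cols - 0.5) * cs,
          lat = grid@yOrigin - (rows - 0.5) * cs)
  }
}

#' Cell index containing a geographic point
#'
#' @param grid a [GeoGrid-class].
#' @param lon,lat coordinates in decimal degrees.
#' @return integer vector `c(row, col)`, or an error of class
#'   `pcPlacementError` if the point falls outside the grid.
#' @export
cellIndexAt <- function(grid, lon, lat) {
  cs <- grid@cellSize
  col <- floor((lon - grid@xOrigin) / cs) + 1L
  row <- floor((grid@yOrigin - lat) / cs) + 1L
  if (row < 1L || row > nrow(grid@values) || col < 1L || col > ncol(grid@values))
    pcStop("pcPlacementError",
           sprintf("point (%.6g, %.6g) falls outside the grid extent", lon, lat))
  c(row = as.integer(row), col = as.integer(col))
}

#' Do two grids share geometry?
#'
#' Identical shape, origin (to 1e-9 of a cell) and cell size.
#'
#' @param a,b [GeoGrid-class] objects.
#' @return logical scalar.
#' @export
sameGeometry <- function(a, b) {
  tol <- 1e-9 * a@cellSize
  identical(dim(a@values), dim(b@values)) &&
    abs(a@cellSize - b@cellSize) <= tol &&
    abs(a@xOrigin - b@xOrigin) <= tol &&
    abs(a@yOrigin - b@yOrigin) <= tol
}

#' @noRd
checkSameGeometry <- function(a, b, what = "grids") {
  if (!sameGeometry(a, b))
    pcStop("pcAlignmentError", sprintf("%s do not share geometry", what))
  invisible(TRUE)
}

#' Summary statistics over a grid region
#'
#' Minimum, mean and maximum of the non-nodata cells, optionally restricted
#' to the open cells of a region [Mask-class]. This is the numeric reduction
#' used when reporting epoch climate layers over a study region.
#'
#' @param grid a [GeoGrid-class].
#' @param region optional [Mask-class]; only open (0) cells are summarised.
#' @return one-row data.frame with columns `n`, `min`, `mean`, `max`.
#' @export
gridSummary <- function(grid, region = NULL) {
  v <- grid@values
  if (!is.null(region)) {
    checkSameGeometry(grid, region, "grid and region mask")
    v[region@values == 1] <- NA
  }
  fin <- v[!is.na(v)]
  if (!length(fin))
    pcStop("pcEmptyInputError", "no data cells in the requested region")
  data.frame(n = length(fin), min = min(fin), mean = mean(fin), max = max(fin))
}
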