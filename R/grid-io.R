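#' Read a georeferenced raster
#'
#' Supported dialects are the ESRI ASCII grid (`.asc`) and a plain
#' single-band uncompressed GeoTIFF. Nodata sentinels become `NA` in memory;
#' the sentinel itself is kept in the [GeoGrid-class] for writing back.
#'
#' @param path file to read.
#' @param dialect `"ascii_grid"` or `"geotiff"`; defaults from the file
#'   extension (`.tif`/`.tiff` vs anything else).
#' @return a [GeoGrid-class].
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeGrid(GeoGrid(matrix(100, 3, 3)), f)
#' readGrid(f)
#' @export
readGrid <- function(path, dialect = c("auto", "ascii_grid", "geotiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "geotiff" else "ascii_grid"
  if (!file.exists(path))
    pcStop("pcIOError", sprintf("file not found: %s", path))
  switch(dialect,
         ascii_grid = readAsciiGrid(path),
         geotiff = readGeoTiff(path))
}

#' Write a georeferenced raster
#'
#' The ASCII dialect writes values with 6 significant digits, the documented
#' bit-exactness boundary for round trips; the GeoTIFF dialect stores IEEE
#' doubles and round-trips exactly. `NA` cells are encoded with the grid's
#' nodata sentinel.
#'
#' @param grid a [GeoGrid-class].
#' @param path destination file.
#' @param dialect `"ascii_grid"` or `"geotiff"` (default from extension).
#' @return `path`, invisibly.
#' @export
writeGrid <- function(grid, path, dialect = c("auto", "ascii_grid", "geotiff")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "geotiff" else "ascii_grid"
  validObject(grid)
  switch(dialect,
         ascii_grid = writeAsciiGrid(grid, path),
         geotiff = writeGeoTiff(grid, path))
  invisible(path)
}

# -- ESRI ASCII grid ---------------------------------------------------------

#' @noRd
readAsciiGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L)
    pcStop("pcFormatError", "ASCII grid too short for a 6-line header")
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    pcStop("pcFormatError",
           sprintf("ASCII grid header missing field(s): %s",
                   paste(miss, collapse = ", ")))
  if (hdr$cellsize <= 0)
    pcStop("pcFormatError", "ASCII grid header field 'cellsize' must be > 0")
  if (hdr$ncols < 1 || hdr$nrows < 1 ||
      hdr$ncols != round(hdr$ncols) || hdr$nrows != round(hdr$nrows))
    pcStop("pcFormatError", "ASCII grid header fields ncols/nrows invalid")
  if (!is.null(hdr$dx) || !is.null(hdr$dy))
    pcStop("pcUnsupportedDialectError",
           "non-square (dx/dy) ASCII grids are not supported")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  # lower-left corner given either as cell corner or cell center
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - hdr$cellsize / 2
  else pcStop("pcFormatError", "ASCII grid header missing field 'xllcorner'")
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - hdr$cellsize / 2
  else pcStop("pcFormatError", "ASCII grid header missing field 'yllcorner'")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  tok <- unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+"),
                use.names = FALSE)
  tok <- tok[nzchar(tok)]
  vals <- suppressWarnings(as.numeric(tok))
  if (anyNA(vals))
    pcStop("pcFormatError", "ASCII grid body contains non-numeric tokens")
  if (length(vals) != nr * nc)
    pcStop("pcFormatError",
           sprintf("ASCII grid body has %d values, expected %d (nrows x ncols)",
                   length(vals), nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  GeoGrid(m, xOrigin = xll, yOrigin = yll + nr * hdr$cellsize,
          cellSize = hdr$cellsize, nodata = nodata)
}

#' @noRd
writeAsciiGrid <- function(grid, path) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  con <- tryCatch(file(path, "w"), error = function(e)
    pcStop("pcIOError", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid@xOrigin),
           sprintf("yllcorner %.10g", grid@yOrigin - nr * grid@cellSize),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", grid@nodata))
  v[is.na(v)] <- grid@nodata
  body <- apply(v, 1L, function(row) paste(sprintf("%.6g", row), collapse = " "))
  ok <- tryCatch({ writeLines(c(hdr, body), con); TRUE },
                 error = function(e) FALSE)
  if (!ok) pcStop("pcIOError", sprintf("failed writing '%s'", path))
  invisible(path)
}

# -- alignment ---------------------------------------------------------------

#' Resample a grid onto a reference geometry
#'
#' Samples `other` at the cell centers of `reference` by nearest-neighbor or
#' bilinear interpolation. Output cells whose sampling point falls outside
#' `other` (or, for bilinear, whose four support cells include nodata) are
#' nodata. Used to co-register climate layers with the DEM.
#'
#' @param reference [GeoGrid-class] defining the output geometry.
#' @param other [GeoGrid-class] to resample.
#' @param method `"nearest"` or `"bilinear"`.
#' @return a [GeoGrid-class] with `reference`'s geometry.
#' @export
alignTo <- function(reference, other, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  ctr <- cellCenters(reference)
  nrR <- nrow(reference@values); ncR <- ncol(reference@values)
  cs <- other@cellSize
  # fractional (0-based) position of reference centers in `other` index space
  fc <- (ctr$lon - other@xOrigin) / cs - 0.5        # per output column
  fr <- (other@yOrigin - ctr$lat) / cs - 0.5        # per output row
  nrO <- nrow(other@values); ncO <- ncol(other@values)
  if (max(fc) < -0.5 || min(fc) > ncO - 0.5 ||
      max(fr) < -0.5 || min(fr) > nrO - 0.5)
    pcStop("pcAlignmentError", "grid extents do not overlap")
  FR <- matrix(fr, nrR, ncR)            # row position varies down rows
  FC <- matrix(fc, nrR, ncR, byrow = TRUE)
  out <- matrix(NA_real_, nrR, ncR)
  if (method == "nearest") {
    ri <- round(FR) + 1; ci <- round(FC) + 1
    ok <- ri >= 1 & ri <= nrO & ci >= 1 & ci <= ncO
    out[ok] <- other@values[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(FR); c0 <- floor(FC)
    tr <- FR - r0; tc <- FC - c0
    # snap to the grid line when the sample point sits on a source center,
    # so aligning a grid to itself is the identity even on the last row/col
    eps <- 1e-9
    snapR <- tr < eps; r1 <- r0 + 1; r1[snapR] <- r0[snapR]; tr[snapR] <- 0
    snapC <- tc < eps; c1 <- c0 + 1; c1[snapC] <- c0[snapC]; tc[snapC] <- 0
    ok <- r0 >= 0 & r1 <= nrO - 1 & c0 >= 0 & c1 <= ncO - 1
    idx <- function(r, c) cbind(r[ok] + 1, c[ok] + 1)
    v00 <- other@values[idx(r0, c0)]; v01 <- other@values[idx(r0, c1)]
    v10 <- other@values[idx(r1, c0)]; v11 <- other@values[idx(r1, c1)]
    w <- (1 - tr[ok]) * (1 - tc[ok]) * v00 + (1 - tr[ok]) * tc[ok] * v01 +
      tr[ok] * (1 - tc[ok]) * v10 + tr[ok] * tc[ok] * v11
    out[ok] <- w
  }
  GeoGrid(out, xOrigin = reference@xOrigin, yOrigin = reference@yOrigin,
          cellSize = reference@cellSize, nodata = reference@nodata)
}
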