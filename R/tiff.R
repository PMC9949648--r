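# Minimal single-band GeoTIFF support, written against the classic TIFF 6.0
# layout: uncompressed, strip-organised, one sample per pixel, IEEE floats.
# Georeference is carried by ModelPixelScale (33550), ModelTiepoint (33922),
# a 3-key GeoKeyDirectory (34735: WGS84 geographic, pixel-is-area) and the
# GDAL_NODATA ASCII tag (42113). Anything fancier (tiles, compression,
# multiple bands) is rejected with a format error rather than misread.

.TIFF_TYPE_SIZE <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8) # BYTE..DOUBLE

#' @noRd
readGeoTiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) pcStop("pcFormatError", "GeoTIFF: file too short")
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    pcStop("pcFormatError", "GeoTIFF: bad byte-order mark")
  int <- function(off, size, n = 1L)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size >= 4, endian = endian) # 4-byte reads are signed;
  # TIFF offsets here stay far below 2^31 so the sign never bites
  dbl <- function(off, n = 1L)
    readBin(raw[(off + 1):(off + 8 * n)], "double", n = n, endian = endian)
  if (int(2, 2) != 42L) pcStop("pcFormatError", "GeoTIFF: bad magic number")
  ifdOff <- int(4, 4)
  nEntries <- int(ifdOff, 2)
  tags <- list()
  for (k in seq_len(nEntries)) {
    e <- ifdOff + 2 + (k - 1) * 12
    tag <- int(e, 2); type <- int(e + 2, 2); count <- int(e + 4, 4)
    size <- .TIFF_TYPE_SIZE[type]
    valOff <- if (size * count <= 4) e + 8 else int(e + 8, 4)
    val <- switch(as.character(type),
      `3` = int(valOff, 2, count),                       # SHORT
      `4` = int(valOff, 4, count),                       # LONG
      `2` = rawToChar(raw[(valOff + 1):(valOff + count)]), # ASCII
      `12` = dbl(valOff, count),                         # DOUBLE
      `11` = readBin(raw[(valOff + 1):(valOff + 4 * count)], "double",
                     n = count, size = 4, endian = endian), # FLOAT
      NULL)
    tags[[as.character(tag)]] <- val
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default))
        pcStop("pcFormatError", sprintf("GeoTIFF: missing required tag %d", id))
      default
    } else v
  }
  nc <- need(256); nr <- need(257)
  bits <- need(258, 32)
  if (need(259, 1) != 1)
    pcStop("pcFormatError", "GeoTIFF: only uncompressed data supported")
  if (need(277, 1) != 1)
    pcStop("pcFormatError", "GeoTIFF: only single-band rasters supported")
  sampleFormat <- need(339, 1)
  if (!is.null(tags[["322"]]))
    pcStop("pcFormatError", "GeoTIFF: tiled layout not supported")
  stripOffsets <- need(273)
  stripCounts <- need(279)
  scale <- need(33550)
  if (abs(scale[1] - scale[2]) > 1e-9 * abs(scale[1]))
    pcStop("pcUnsupportedDialectError",
           "GeoTIFF: non-square cells are not supported")
  tie <- need(33922)
  if (length(tie) < 6 || any(tie[1:2] != 0))
    pcStop("pcFormatError", "GeoTIFF: expected a (0,0) raster tiepoint")
  bytesPer <- bits / 8
  vals <- numeric(0)
  for (s in seq_along(stripOffsets)) {
    n <- stripCounts[s] / bytesPer
    seg <- raw[(stripOffsets[s] + 1):(stripOffsets[s] + stripCounts[s])]
    vals <- c(vals, if (sampleFormat == 3)
      readBin(seg, "double", n = n, size = bytesPer, endian = endian)
      else readBin(seg, "integer", n = n, size = bytesPer, signed = TRUE,
                   endian = endian))
  }
  if (length(vals) != nr * nc)
    pcStop("pcFormatError", "GeoTIFF: pixel count disagrees with dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- suppressWarnings(as.numeric(gsub("\\0", "", need(42113, "NaN"))))
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  m[is.nan(m)] <- NA_real_
  GeoGrid(m, xOrigin = tie[4], yOrigin = tie[5], cellSize = scale[1],
          nodata = if (is.na(nodata)) -9999 else nodata)
}

#' @noRd
writeGeoTiff <- function(grid, path) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  v[is.na(v)] <- grid@nodata
  pix <- as.vector(t(v)) # row-major
  dataOff <- 8L
  dataLen <- 8L * nr * nc
  ifdOff <- dataOff + dataLen
  nodataStr <- sprintf("%.10g", grid@nodata)
  nodataRaw <- c(charToRaw(nodataStr), as.raw(0))
  geoKeys <- as.integer(c(
    1, 1, 0, 3,        # version, revision, minor, key count
    1024, 0, 1, 2,     # GTModelType = geographic
    1025, 0, 1, 1,     # GTRasterType = pixel-is-area
    2048, 0, 1, 4326)) # GeographicType = WGS84
  entries <- list( # tag, type, count, value (inline int) or list(offset data)
    list(256, 4, 1, nc),
    list(257, 4, 1, nr),
    list(258, 3, 1, 64),
    list(259, 3, 1, 1),
    list(262, 3, 1, 1),
    list(273, 4, 1, dataOff),
    list(277, 3, 1, 1),
    list(278, 4, 1, nr),
    list(279, 4, 1, dataLen),
    list(339, 3, 1, 3),
    list(33550, 12, 3, c(grid@cellSize, grid@cellSize, 0)),
    list(33922, 12, 6, c(0, 0, 0, grid@xOrigin, grid@yOrigin, 0)),
    list(34735, 3, length(geoKeys), geoKeys),
    list(42113, 2, length(nodataRaw), nodataRaw)
  )
  nE <- length(entries)
  extOff <- ifdOff + 2L + nE * 12L + 4L
  con <- tryCatch(file(path, "wb"), error = function(e)
    pcStop("pcIOError", sprintf("cannot open '%s' for writing", path)))
  on.exit(close(con))
  w8 <- function(x) writeBin(as.integer(x), con, size = 1, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, nchars = 2, eos = NULL)
  w16(42); w32(ifdOff)
  writeBin(pix, con, size = 8, endian = "little")
  w16(nE)
  ext <- list(); cur <- extOff
  for (e in entries) {
    tag <- e[[1]]; type <- e[[2]]; count <- e[[3]]; val <- e[[4]]
    size <- .TIFF_TYPE_SIZE[type] * count
    w16(tag); w16(type); w32(count)
    if (type %in% c(3, 4) && size <= 4) {
      # inline integer value, left-justified in the 4-byte slot
      if (type == 3) { w16(val); w16(0) } else w32(val)
    } else {
      w32(cur)
      ext[[length(ext) + 1]] <- list(type, val)
      cur <- cur + size + (size %% 2) # word-align
    }
  }
  w32(0) # no next IFD
  for (x in ext) {
    type <- x[[1]]; val <- x[[2]]
    size <- switch(as.character(type),
                   `2` = { writeBin(val, con); length(val) },
                   `3` = { w16(val); 2L * length(val) },
                   `12` = { writeBin(as.numeric(val), con, size = 8,
                                     endian = "little"); 8L * length(val) })
    if (size %% 2) w8(0)
  }
  invisible(path)
}
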