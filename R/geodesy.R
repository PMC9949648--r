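#' Great-circle distance (haversine)
#'
#' Haversine distance on the mean-Earth-radius sphere (R = 6371.0088 km).
#' Vectorised over all arguments.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance in km.
#' @examples
#' haversineKm(0, 0, 1, 0) # ~111.195 km: one degree along the equator
#' @export
haversineKm <- function(lon1, lat1, lon2, lat2) {
  toRad <- pi / 180
  dLat <- (lat2 - lat1) * toRad
  dLon <- (lon2 - lon1) * toRad
  a <- sin(dLat / 2)^2 +
    cos(lat1 * toRad) * cos(lat2 * toRad) * sin(dLon / 2)^2
  2 * .EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' @noRd
bearingRad <- function(lon1, lat1, lon2, lat2) {
  toRad <- pi / 180
  dLon <- (lon2 - lon1) * toRad
  y <- sin(dLon) * cos(lat2 * toRad)
  x <- cos(lat1 * toRad) * sin(lat2 * toRad) -
    sin(lat1 * toRad) * cos(lat2 * toRad) * cos(dLon)
  atan2(y, x)
}

# Minimum great-circle distance (km) from point P to the arc A--B, clipped to
# the segment: cross-track distance when the along-track foot falls within
# the segment, otherwise the nearer endpoint distance.
#' @noRd
pointSegmentKm <- function(lonP, latP, lonA, latA, lonB, latB) {
  dAP <- haversineKm(lonA, latA, lonP, latP)
  dAB <- haversineKm(lonA, latA, lonB, latB)
  if (dAB == 0) return(dAP)
  if (dAP == 0) return(0)
  th13 <- bearingRad(lonA, latA, lonP, latP)
  th12 <- bearingRad(lonA, latA, lonB, latB)
  d13 <- dAP / .EARTH_RADIUS_KM
  dxt <- asin(pmin(1, pmax(-1, sin(d13) * sin(th13 - th12))))
  if (cos(th13 - th12) < 0) return(dAP) # foot before A
  dat <- acos(pmin(1, pmax(-1, cos(d13) / cos(dxt))))
  if (dat > dAB / .EARTH_RADIUS_KM) # foot beyond B
    return(haversineKm(lonB, latB, lonP, latP))
  abs(dxt) * .EARTH_RADIUS_KM
}

#' Minimum distance from points to a polyline
#'
#' Great-circle distance from each query point to the nearest point of the
#' polyline, measured against segments (not just vertices).
#'
#' @param coords n x 2 matrix of polyline vertex (lon, lat).
#' @param lon,lat query point coordinates (vectorised).
#' @return numeric vector of distances in km.
#' @export
distanceToPathKm <- function(coords, lon, lat) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  vapply(seq_along(lon), function(i) {
    if (n == 1L)
      return(haversineKm(coords[1, 1], coords[1, 2], lon[i], lat[i]))
    min(vapply(seq_len(n - 1L), function(s)
      pointSegmentKm(lon[i], lat[i],
                     coords[s, 1], coords[s, 2],
                     coords[s + 1L, 1], coords[s + 1L, 2]),
      numeric(1)))
  }, numeric(1))
}
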