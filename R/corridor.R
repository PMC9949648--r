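#' Settlement-potential corridor around a dispersal path
#'
#' A point belongs to the corridor when its minimum great-circle distance to
#' any path segment (not just vertices) is at most `bufferKm`. The default
#' 30 km half-width delimits the zone of highly potential hominin
#' settlements along a route.
#'
#' @param path a [DispersalPath-class] or an n x 2 (lon, lat) matrix of
#'   vertices (n >= 1).
#' @param bufferKm positive buffer radius in km (default 30).
#' @return a [Corridor-class].
#' @export
bufferCorridor <- function(path, bufferKm = 30) {
  if (length(bufferKm) != 1L || !is.finite(bufferKm) || bufferKm <= 0)
    pcStop("pcParameterError", "bufferKm must be a single positive number")
  if (is(path, "DispersalPath")) {
    coords <- path@coords
    src <- sprintf("%s->%s", path@start, path@end)
  } else {
    coords <- as.matrix(path)
    src <- "coordinates"
  }
  if (nrow(coords) < 1L)
    pcStop("pcParameterError", "path must have at least one vertex")
  new("Corridor", coords = coords, bufferKm = bufferKm, source = src)
}

setMethod("show", "Corridor", function(object) {
  cat(sprintf("Corridor: %.6g km buffer around %s (%d vertices)\n",
              object@bufferKm, object@source, nrow(object@coords)))
  invisible(object)
})

#' Corridor membership of points
#'
#' @param corridor a [Corridor-class].
#' @param lon,lat query coordinates (vectorised).
#' @return logical vector; attribute `"distanceKm"` carries the distances.
#' @export
inCorridor <- function(corridor, lon, lat) {
  d <- distanceToPathKm(corridor@coords, lon, lat)
  structure(d <= corridor@bufferKm, distanceKm = d)
}

#' Sites inside a corridor
#'
#' Filters a site table to the sites whose distance to the path is within
#' the buffer, annotates each with its distance, and orders by distance
#' (ties by name).
#'
#' @param sites a site table (see [readSites()]): data.frame with columns
#'   `name`, `lon`, `lat`, `culture`, `role`.
#' @param corridor a [Corridor-class].
#' @return the qualifying rows with an extra `distance_km` column, ordered
#'   by distance then name; zero rows is a valid result.
#' @export
sitesInCorridor <- function(sites, corridor) {
  sites <- validateSites(sites)
  if (!nrow(sites)) {
    sites$distance_km <- numeric(0)
    return(sites)
  }
  d <- distanceToPathKm(corridor@coords, sites$lon, sites$lat)
  keep <- d <= corridor@bufferKm
  out <- sites[keep, , drop = FALSE]
  out$distance_km <- d[keep]
  out <- out[order(out$distance_km, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
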