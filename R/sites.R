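#' Read and validate a site table
#'
#' Sites are archaeological locations anchoring routes: CSV with header
#' `name,lon,lat,culture,role`. `culture` is one of `Micoquian`,
#' `Mousterian`, `other`; `role` one of `start`, `end`, `waypoint`,
#' `candidate`. Names must be unique, longitudes in \[-180, 180\] and
#' latitudes in \[-90, 90\].
#'
#' @param path CSV file.
#' @return validated data.frame.
#' @export
readSites <- function(path) {
  if (!file.exists(path))
    pcStop("pcIOError", sprintf("site table not found: %s", path))
  validateSites(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname readSites
#' @param sites data.frame to validate in place.
#' @export
validateSites <- function(sites) {
  need <- c("name", "lon", "lat", "culture", "role")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    pcStop("pcFormatError",
           sprintf("site table missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(sites$name))
    pcStop("pcFormatError", "site names must be unique")
  if (nrow(sites)) {
    if (any(sites$lon < -180 | sites$lon > 180) ||
        any(sites$lat < -90 | sites$lat > 90))
      pcStop("pcFormatError", "site coordinates outside valid lon/lat ranges")
    badC <- setdiff(unique(sites$culture), c("Micoquian", "Mousterian", "other"))
    if (length(badC))
      pcStop("pcFormatError",
             sprintf("unknown culture value(s): %s", paste(badC, collapse = ", ")))
    badR <- setdiff(unique(sites$role), c("start", "end", "waypoint", "candidate"))
    if (length(badR))
      pcStop("pcFormatError",
             sprintf("unknown role value(s): %s", paste(badR, collapse = ", ")))
  }
  sites[need]
}

#' @rdname readSites
#' @param file destination CSV.
#' @export
writeSites <- function(sites, file) {
  write.csv(validateSites(sites), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
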