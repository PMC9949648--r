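# Seeded synthetic landscape emulating the study geography: two east-west
# mountain ranges (Greater Caucasus / Alborz analogs) separated by a closed
# sea basin whose floor lies below every published stand, a narrow low
# coastal strip between the southern range and the sea (the Southern Caspian
# Corridor analog), desert lobes flanking the corridor east of the sea
# (Karakum / inner-desert analogs), and start/end sites mirroring the
# Mezmaiskaya / Azokh / Altai / Teshik-Tash configuration.

#' Default parameters of the synthetic landscape
#'
#' Returns the parameter list consumed by [generateLandscape()]. The default
#' grid is 200 x 400 cells at 0.1 degrees (lon 40-80, lat 30-50): large
#' enough for two distinct routes around the sea, small enough for
#' seconds-scale tests. Heights, stand depths and widths are chosen so every
#' published Caspian stand is realisable (basin floor -200 m) and the
#' corridor strip stays routable (>= 3 cells wide).
#'
#' @param seed RNG seed for the band-limited noise field.
#' @param nRows,nCols,cellSize,xOrigin,yOrigin grid geometry.
#' @param baseElev plains elevation (m asl).
#' @param northernRange,southernRange lists with `lat` (crest center-line),
#'   `height` (m) and `sigma` (Gaussian half-width, degrees).
#' @param seaCenter,seaRadius basin ellipse center (lon, lat) and semi-axes
#'   (degrees); `seaFloor` the floor depth (m asl, below -140 so all stands
#'   are realisable); `shelfSlope` the subaerial shelf gradient (m per
#'   degree) ringing the basin.
#' @param corridor list describing the low coastal strip: `lonRange`,
#'   `latRange`, `floorElev` (m asl).
#' @param channel list connecting strip to basin so transgressions flood the
#'   strip: `lonRange`, `latRange`, elevations interpolated `fromElev` (at
#'   the strip) to `toElev` (at the basin).
#' @param desertNorth,desertSouth rectangular desert lobes (lon/lat ranges)
#'   flanking the corridor.
#' @param noiseSd standard deviation (m) of the band-limited terrain noise;
#'   `noiseScale` its correlation scale in cells.
#' @param sites data.frame of site analogs placed on the landscape.
#' @return named list of parameters.
#' @export
landscapeParams <- function(seed = 7L,
                            nRows = 200L, nCols = 400L, cellSize = 0.1,
                            xOrigin = 40, yOrigin = 50,
                            baseElev = 150,
                            northernRange = list(lat = 48, height = 2500, sigma = 0.7),
                            southernRange = list(lat = 34.5, height = 3000, sigma = 0.7),
                            seaCenter = c(47, 41), seaRadius = c(8, 4.5),
                            seaFloor = -200, shelfSlope = 500,
                            corridor = list(lonRange = c(50, 80),
                                            latRange = c(35.1, 35.9),
                                            floorElev = 30),
                            channel = list(lonRange = c(50, 51.5),
                                           latRange = c(35.9, 38.8),
                                           fromElev = 40, toElev = -80),
                            desertNorth = list(lonRange = c(57, 74),
                                               latRange = c(35.9, 43.5)),
                            desertSouth = list(lonRange = c(57, 80),
                                               latRange = c(30, 34.8)),
                            noiseSd = 10, noiseScale = 3,
                            sites = NULL) {
  if (is.null(sites)) {
    sites <- data.frame(
      name = c("NorthwestCave", "SouthwestCave", "EastCave",
               "MidCorridorShelter", "CoastalCamp", "NorthPlainCamp"),
      lon = c(42.0, 43.5, 79.3, 62.0, 46.0, 60.0),
      lat = c(47.0, 35.5, 35.5, 35.5, 35.4, 46.0),
      culture = c("Micoquian", "Mousterian", "other",
                  "Mousterian", "other", "other"),
      role = c("start", "start", "end", "waypoint", "candidate", "candidate"),
      stringsAsFactors = FALSE
    )
  }
  params <- list(seed = seed, nRows = nRows, nCols = nCols,
                 cellSize = cellSize, xOrigin = xOrigin, yOrigin = yOrigin,
                 baseElev = baseElev, northernRange = northernRange,
                 southernRange = southernRange, seaCenter = seaCenter,
                 seaRadius = seaRadius, seaFloor = seaFloor,
                 shelfSlope = shelfSlope, corridor = corridor,
                 channel = channel, desertNorth = desertNorth,
                 desertSouth = desertSouth, noiseSd = noiseSd,
                 noiseScale = noiseScale, sites = sites)
  if (!is.null(corridor)) {
    widthCells <- diff(corridor$latRange) / cellSize
    if (widthCells < 3)
      pcStop("pcParameterError",
             "corridor strip must be at least 3 cells wide to stay routable")
  }
  if (seaFloor >= -140)
    pcStop("pcParameterError",
           "sea floor must lie below -140 m so all published stands are realisable")
  params
}

# Band-limited (Gaussian-smoothed) noise: white noise filtered with a
# separable Gaussian kernel and rescaled, so slope fields stay realistic and
# flood fill is stable.
#' @noRd
smoothNoise <- function(nr, nc, sd, scaleCells, seed) {
  if (sd <= 0) return(matrix(0, nr, nc))
  set.seed(seed)
  w <- matrix(rnorm(nr * nc), nr, nc)
  half <- max(1L, ceiling(3 * scaleCells))
  k <- exp(-(seq(-half, half))^2 / (2 * scaleCells^2))
  k <- k / sum(k)
  pad <- function(m, n) m[pmin(pmax(seq_len(nrow(m) + 2 * n) - n, 1), nrow(m)), ,
                          drop = FALSE]
  convRows <- function(m) {
    mp <- pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k))
      out <- out + k[i] * mp[seq_len(nrow(m)) + (i - 1L), , drop = FALSE]
    out
  }
  sm <- t(convRows(t(convRows(w))))
  sm / stats::sd(sm) * sd
}

#' @noRd
rectRing <- function(lonRange, latRange) {
  cbind(lon = c(lonRange[1], lonRange[2], lonRange[2], lonRange[1]),
        lat = c(latRange[1], latRange[1], latRange[2], latRange[2]))
}

#' Generate the synthetic landscape
#'
#' Builds the DEM (Gaussian-profile ridges + excavated sea basin + corridor
#' strip + seeded band-limited noise), the default barrier scenario (the
#' MIS 4 Atelian lowstand at -140 m with both desert lobes), and the site
#' table. The same seed reproduces the landscape bit-exactly.
#'
#' @param params parameter list from [landscapeParams()].
#' @return list with elements `dem` ([GeoGrid-class]), `scenario`
#'   ([BarrierScenario-class]), `sites` (data.frame), and `params`.
#' @examples
#' land <- generateLandscape(landscapeParams(seed = 7))
#' land$dem
#' @export
generateLandscape <- function(params = landscapeParams()) {
  nr <- params$nRows; nc <- params$nCols; cs <- params$cellSize
  lon <- params$xOrigin + (seq_len(nc) - 0.5) * cs
  lat <- params$yOrigin - (seq_len(nr) - 0.5) * cs
  LON <- matrix(lon, nr, nc, byrow = TRUE)
  LAT <- matrix(lat, nr, nc)
  ridge <- function(rg) rg$height * exp(-(LAT - rg$lat)^2 / (2 * rg$sigma^2))
  z <- params$baseElev + ridge(params$northernRange) + ridge(params$southernRange) +
    smoothNoise(nr, nc, params$noiseSd, params$noiseScale, params$seed)
  # excavate the closed sea basin: parabolic bowl to the floor inside the
  # ellipse, a gentle shelf ring outside it
  rho <- sqrt(((LON - params$seaCenter[1]) / params$seaRadius[1])^2 +
              ((LAT - params$seaCenter[2]) / params$seaRadius[2])^2)
  bowl <- params$seaFloor * (1 - rho^2)            # floor at center, 0 at rim
  shelf <- params$shelfSlope * (rho - 1)           # rises off the rim
  basin <- ifelse(rho <= 1, bowl, shelf)
  carve <- rho <= 1.3
  z[carve] <- pmin(z[carve], basin[carve])
  # the low coastal corridor strip south of the sea (SCC analog)
  co <- params$corridor
  inStrip <- LON >= co$lonRange[1] & LON <= co$lonRange[2] &
    LAT >= co$latRange[1] & LAT <= co$latRange[2]
  z[inStrip] <- pmin(z[inStrip], co$floorElev)
  # channel connecting strip and basin, so transgressions drown the strip
  ch <- params$channel
  inCh <- LON >= ch$lonRange[1] & LON <= ch$lonRange[2] &
    LAT >= ch$latRange[1] & LAT <= ch$latRange[2]
  frac <- (LAT - ch$latRange[1]) / diff(ch$latRange)
  chElev <- ch$fromElev + frac * (ch$toElev - ch$fromElev)
  z[inCh] <- pmin(z[inCh], chElev[inCh])
  # site knolls keep the waypoint and eastern terminus above the strip floor
  knoll <- function(z, center, height, sigma) {
    d2 <- (LON - center[1])^2 + (LAT - center[2])^2
    k <- height * exp(-d2 / (2 * sigma^2))
    on <- k > 1 # leave the far field (and the basin) untouched
    z[on] <- pmax(z[on], k[on])
    z
  }
  z <- knoll(z, c(62.0, 35.5), 100, 0.10)   # mid-corridor shelter
  z <- knoll(z, c(79.3, 35.5), 400, 0.12)   # eastern terminus
  dem <- GeoGrid(z, xOrigin = params$xOrigin, yOrigin = params$yOrigin,
                 cellSize = cs)
  scenario <- barrierScenario(
    name = "MIS4-Atelian", seaLevel = caspianStands()[["atelian_low"]],
    seaSeed = params$seaCenter,
    barrierPolygons = list(
      karakum = rectRing(params$desertNorth$lonRange, params$desertNorth$latRange),
      innerDesert = rectRing(params$desertSouth$lonRange, params$desertSouth$latRange)
    ))
  sites <- validateSites(params$sites)
  mask <- scenarioMask(dem, scenario)
  bm <- blockedCells(mask)
  for (i in seq_len(nrow(sites))) {
    idx <- cellIndexAt(dem, sites$lon[i], sites$lat[i])
    if (bm[idx[1], idx[2]])
      pcStop("pcGenerationError",
             sprintf("site '%s' falls on a blocked cell under the default scenario",
                     sites$name[i]))
  }
  list(dem = dem, scenario = scenario, sites = sites, params = params)
}

#' Generate a synthetic climate epoch pair
#'
#' Temperature decreases with elevation at a fixed lapse rate; the newer
#' epoch is uniformly colder by `epochalCooling` (LIG to LGM analog). Noise
#' is white per cell and independent between epochs.
#'
#' @param dem [GeoGrid-class] of elevation.
#' @param seaLevelT temperature at 0 m asl, degrees C (default 15).
#' @param lapsePerKm lapse rate, degrees C per km of elevation (default 6.5).
#' @param epochalCooling cooling from old to new epoch, degrees C (default
#'   5, a glacial-scale mid-latitude cooling).
#' @param noiseSd per-cell noise sd in degrees C (default 0).
#' @param seed RNG seed.
#' @param deltaYears years between the epochs (default 110000).
#' @return a [ClimateEpochPair-class] co-registered with `dem`.
#' @export
generateClimate <- function(dem, seaLevelT = 15, lapsePerKm = 6.5,
                            epochalCooling = 5, noiseSd = 0, seed = 7L,
                            deltaYears = 110000) {
  z <- dem@values
  set.seed(seed)
  mkNoise <- function() if (noiseSd > 0)
    matrix(rnorm(length(z), sd = noiseSd), nrow(z), ncol(z)) else 0
  tOldV <- seaLevelT - lapsePerKm * (z / 1000) + mkNoise()
  tNewV <- tOldV - epochalCooling + mkNoise()
  tOldV[is.na(z)] <- NA_real_; tNewV[is.na(z)] <- NA_real_
  mk <- function(v) GeoGrid(v, xOrigin = dem@xOrigin, yOrigin = dem@yOrigin,
                            cellSize = dem@cellSize, nodata = dem@nodata)
  climateEpochPair(mk(tOldV), mk(tNewV), deltaYears)
}
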