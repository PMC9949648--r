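#' Read / write barrier scenarios as YAML
#'
#' Scenario files carry keys `name`, `sea_level_m`, `sea_seed` (lon, lat),
#' `min_suitable_elev_m`, `max_suitable_elev_m`, `barrier_polygons` (path to
#' a GeoJSON of desert polygons, relative to the YAML file) and
#' `apply_band`.
#'
#' @param path YAML file.
#' @return a [BarrierScenario-class].
#' @export
readScenario <- function(path) {
  if (!file.exists(path))
    pcStop("pcIOError", sprintf("scenario file not found: %s", path))
  y <- yaml::read_yaml(path)
  polys <- list()
  if (!is.null(y$barrier_polygons)) {
    pp <- y$barrier_polygons
    if (!file.exists(pp)) pp <- file.path(dirname(path), y$barrier_polygons)
    polys <- readPolygonsGeoJSON(pp)
  }
  barrierScenario(
    name = y$name %||% "unnamed",
    seaLevel = y$sea_level_m,
    seaSeed = unlist(y$sea_seed),
    minSuitableElev = y$min_suitable_elev_m %||% 50,
    maxSuitableElev = y$max_suitable_elev_m %||% 1800,
    barrierPolygons = polys,
    applyBand = isTRUE(y$apply_band),
    desertCostMultiplier = y$desert_cost_multiplier %||% Inf)
}

#' @rdname readScenario
#' @param scenario a [BarrierScenario-class].
#' @param polygonFile where to write the desert polygons GeoJSON (default
#'   next to the YAML); referenced by basename from the YAML.
#' @export
writeScenario <- function(scenario, path,
                          polygonFile = sub("\\.ya?ml$", "_deserts.geojson", path)) {
  y <- list(name = scenario@name,
            sea_level_m = scenario@seaLevel,
            sea_seed = as.numeric(scenario@seaSeed),
            min_suitable_elev_m = scenario@minSuitableElev,
            max_suitable_elev_m = scenario@maxSuitableElev,
            apply_band = scenario@applyBand)
  if (is.finite(scenario@desertCostMultiplier))
    y$desert_cost_multiplier <- scenario@desertCostMultiplier
  if (length(scenario@barrierPolygons)) {
    writePolygonsGeoJSON(scenario@barrierPolygons, polygonFile)
    y$barrier_polygons <- basename(polygonFile)
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write polygons as GeoJSON
#'
#' Supports `Polygon` and `MultiPolygon` features; rings are returned as
#' n x 2 (lon, lat) matrices (outer rings and holes alike: masks apply the
#' even-odd rule, so holes behave naturally).
#'
#' @param path GeoJSON file.
#' @return named list of polygons; each element is a ring matrix or a list
#'   of ring matrices.
#' @export
readPolygonsGeoJSON <- function(path) {
  if (!file.exists(path))
    pcStop("pcIOError", sprintf("GeoJSON file not found: %s", path))
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    ringMat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    polys <- switch(geom$type,
                    Polygon = list(lapply(geom$coordinates, ringMat)),
                    MultiPolygon = lapply(geom$coordinates,
                                          function(p) lapply(p, ringMat)),
                    pcStop("pcFormatError",
                           sprintf("unsupported GeoJSON geometry '%s'", geom$type)))
    nm <- f$properties$name %||% sprintf("polygon%d", length(out) + 1L)
    for (p in polys) {
      p <- if (length(p) == 1L) p[[1]] else p
      out[[nm]] <- p
      nm <- sprintf("polygon%d", length(out) + 1L)
    }
  }
  out
}

#' @rdname readPolygonsGeoJSON
#' @param polygons named list of ring matrices (or lists of rings).
#' @export
writePolygonsGeoJSON <- function(polygons, path) {
  feats <- lapply(seq_along(polygons), function(i) {
    poly <- polygons[[i]]
    rings <- if (is.list(poly)) poly else list(poly)
    coords <- lapply(rings, function(r) {
      r <- closeRing(as.matrix(r))
      unname(apply(r, 1L, function(p) c(p[[1]], p[[2]]), simplify = FALSE))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(name = names(polygons)[i] %||% sprintf("polygon%d", i)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @noRd
logStage <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[paleocorridor] %-12s %s", stage, sprintf(fmt, ...)))
}

#' Read a run configuration
#'
#' YAML with keys `dem`, `sites`, `scenario` (file paths) or `synthetic:
#' {seed: N}` to generate inputs; `k_slope`, `buffer_km`, `routes` (list of
#' `{start, end}` site-name pairs), `out_dir`, and optional `climate:
#' {t_old, t_new, delta_years, quantile}`.
#'
#' @param path YAML file.
#' @return config list for [runScenario()].
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    pcStop("pcIOError", sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (!is.null(p) && !file.exists(p)) file.path(base, p) else p
  for (k in c("dem", "sites", "scenario")) cfg[[k]] <- rel(cfg[[k]])
  if (!is.null(cfg$climate)) {
    cfg$climate$t_old <- rel(cfg$climate$t_old)
    cfg$climate$t_new <- rel(cfg$climate$t_new)
  }
  cfg
}

#' Run an end-to-end dispersal scenario
#'
#' From one configuration: read (or synthesise) the DEM, scenario and sites;
#' compute slope, barrier masks and the cost surface; route every configured
#' start/end pair; report the corridor membership of all sites per route;
#' optionally compute the climate-velocity map and refugium mask. All
#' outputs are deterministic: identical config and inputs give byte-identical
#' files (no timestamps are recorded).
#'
#' @param config list (or path to a YAML read via [readRunConfig()]) with
#'   elements: `dem`/`sites`/`scenario` file paths *or* `synthetic = list(seed =
#'   N)`; `routes` list of `list(start =, end =)` site-name pairs; `k_slope`
#'   (default 0.1); `buffer_km` (default 30); `out_dir`; optional `climate`
#'   list (`t_old`, `t_new` paths or `synthetic = TRUE`, `delta_years`,
#'   `quantile`); `apply_band` override.
#' @param verbose log one line per stage to stderr.
#' @return the run manifest (list), invisibly written as
#'   `manifest.json` under `out_dir`: per-route total cost, length, corridor
#'   sites, output paths, config echo, input hashes and package version.
#' @export
runScenario <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- readRunConfig(config)
  outDir <- config$out_dir %||% pcStop("pcConfigError", "config needs out_dir")
  kSlope <- config$k_slope %||% 0.1
  bufferKm <- config$buffer_km %||% 30
  routes <- config$routes %||% pcStop("pcConfigError", "config needs routes")

  # ---- load or synthesise inputs (fail fast, before any outputs) ----
  inputHashes <- list()
  if (!is.null(config$synthetic)) {
    seed <- config$synthetic$seed %||% 7L
    land <- generateLandscape(landscapeParams(seed = seed))
    dem <- land$dem; scenario <- land$scenario; sites <- land$sites
    inputHashes$synthetic_seed <- seed
  } else {
    for (k in c("dem", "sites", "scenario"))
      if (is.null(config[[k]]))
        pcStop("pcConfigError", sprintf("config needs '%s' (or synthetic)", k))
    dem <- readGrid(config$dem)
    sites <- readSites(config$sites)
    scenario <- readScenario(config$scenario)
    for (k in c("dem", "sites", "scenario"))
      inputHashes[[k]] <- unname(tools::md5sum(config[[k]]))
  }
  if (!is.null(config$apply_band))
    scenario@applyBand <- isTRUE(config$apply_band)
  for (rt in routes) {
    for (nm in c(rt$start, rt$end))
      if (!nm %in% sites$name)
        pcStop("pcConfigError",
               sprintf("route references unknown site '%s'", nm))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  nCells <- prod(dim(dem))
  logStage(verbose, "inputs", "DEM %d x %d (%d cells), %d sites, scenario '%s'",
           nrow(dem@values), ncol(dem@values), nCells, nrow(sites),
           scenario@name)

  # ---- terrain, barriers, cost ----
  t0 <- proc.time()[3]
  slope <- computeSlope(dem)
  logStage(verbose, "slope", "%d cells in %.2fs", nCells, proc.time()[3] - t0)
  t0 <- proc.time()[3]
  mask <- scenarioMask(dem, scenario)
  logStage(verbose, "barriers", "%d blocked cells in %.2fs",
           sum(blockedCells(mask)), proc.time()[3] - t0)
  soft <- NULL
  if (is.finite(scenario@desertCostMultiplier) &&
      length(scenario@barrierPolygons))
    soft <- polygonMask(dem, scenario@barrierPolygons)
  cost <- buildCostSurface(slope, mask, kSlope = kSlope,
                           softBarrier = soft,
                           softMultiplier = if (is.null(soft)) 1 else
                             scenario@desertCostMultiplier,
                           scenarioName = scenario@name)
  costFile <- file.path(outDir, "cost.asc")
  writeGrid(cost, costFile)

  # ---- routes and corridors ----
  routeReports <- list()
  for (rt in routes) {
    sRow <- sites[sites$name == rt$start, ]
    eRow <- sites[sites$name == rt$end, ]
    t0 <- proc.time()[3]
    path <- leastCostPath(cost, c(sRow$lon, sRow$lat), c(eRow$lon, eRow$lat),
                          startName = rt$start, endName = rt$end,
                          scenarioName = scenario@name)
    logStage(verbose, "lcp", "%s->%s: %d cells, cost %.1f, %.0f km (%.2fs)",
             rt$start, rt$end, nrow(path@cells), path@totalCost,
             path@lengthKm, proc.time()[3] - t0)
    tag <- sprintf("%s_to_%s", rt$start, rt$end)
    pathFile <- file.path(outDir, sprintf("%s_path.geojson", tag))
    writePathGeoJSON(path, pathFile)
    corridor <- bufferCorridor(path, bufferKm)
    inside <- sitesInCorridor(sites, corridor)
    corrFile <- file.path(outDir, sprintf("%s_corridor.csv", tag))
    write.csv(inside, corrFile, row.names = FALSE, quote = FALSE)
    routeReports[[tag]] <- list(
      start = rt$start, end = rt$end,
      total_cost = path@totalCost, length_km = path@lengthKm,
      n_cells = nrow(path@cells),
      corridor_sites = inside$name,
      path_file = basename(pathFile), corridor_file = basename(corrFile))
  }

  # ---- optional climate stability ----
  climateReport <- NULL
  if (!is.null(config$climate)) {
    cc <- config$climate
    pair <- if (isTRUE(cc$synthetic)) {
      generateClimate(dem, seed = (config$synthetic$seed %||% 7L),
                      deltaYears = cc$delta_years %||% 110000)
    } else {
      climateEpochPair(alignTo(dem, readGrid(cc$t_old)),
                       alignTo(dem, readGrid(cc$t_new)),
                       deltaYears = cc$delta_years %||% 110000)
    }
    t0 <- proc.time()[3]
    vel <- climateVelocity(pair)
    stable <- stabilityMask(vel, quantile = cc$quantile %||% 0.25)
    logStage(verbose, "velocity", "%d refugium cells in %.2fs",
             sum(!blockedCells(stable)), proc.time()[3] - t0)
    velFile <- file.path(outDir, "velocity.asc")
    stableFile <- file.path(outDir, "refugia.asc")
    writeGrid(vel, velFile); writeGrid(stable, stableFile)
    climateReport <- list(
      velocity_file = basename(velFile), refugia_file = basename(stableFile),
      n_refugium_cells = sum(!blockedCells(stable)),
      velocity_summary = as.list(gridSummary(vel)))
  }

  manifest <- list(
    package = "paleocorridor",
    version = as.character(packageVersion("paleocorridor")),
    scenario = scenario@name,
    config = config[setdiff(names(config), "out_dir")],
    inputs = inputHashes,
    cost_file = basename(costFile),
    routes = routeReports,
    climate = climateReport)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  logStage(verbose, "manifest", "%d route(s) written to %s",
           length(routeReports), outDir)
  invisible(manifest)
}
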