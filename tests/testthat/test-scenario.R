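syntheticConfig <- function(outDir, routes = NULL, climate = FALSE) {
  cfg <- list(
    synthetic = list(seed = 7L),
    k_slope = 0.1, buffer_km = 30,
    routes = routes %||% list(
      list(start = "NorthwestCave", end = "EastCave"),
      list(start = "SouthwestCave", end = "EastCave")),
    out_dir = outDir)
  if (climate) cfg$climate <- list(synthetic = TRUE, quantile = 0.25)
  cfg
}
`%||%` <- function(a, b) if (is.null(a)) b else a

closeRingForTest <- function(ring) {
  ring <- as.matrix(ring)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

test_that("a synthetic run solves both routes with sane geometry", {
  out <- file.path(tempdir(), "run_a")
  mf <- runScenario(syntheticConfig(out), verbose = FALSE)
  expect_identical(length(mf$routes), 2L)
  for (rt in mf$routes) {
    expect_true(is.finite(rt$total_cost))
    expect_gte(rt$total_cost, rt$length_km) # cost >= 1 everywhere
  }
  # each route is at least as long as the start-end great circle
  land <- generateLandscape(landscapeParams(seed = 7))
  s <- land$sites
  for (rt in mf$routes) {
    a <- s[s$name == rt$start, ]; b <- s[s$name == rt$end, ]
    expect_gte(rt$length_km, haversineKm(a$lon, a$lat, b$lon, b$lat))
  }
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "cost.asc")))
  expect_true(file.exists(file.path(out,
    "SouthwestCave_to_EastCave_path.geojson")))
})

test_that("an unknown route site fails fast with no outputs written", {
  out <- file.path(tempdir(), "run_bad")
  unlink(out, recursive = TRUE)
  cfg <- syntheticConfig(out, routes = list(list(start = "Nowhere",
                                                 end = "EastCave")))
  expect_error(runScenario(cfg, verbose = FALSE), "Nowhere",
               class = "pcConfigError")
  expect_false(dir.exists(out))
})

test_that("reruns of one config are byte-identical", {
  out1 <- file.path(tempdir(), "run_d1")
  out2 <- file.path(tempdir(), "run_d2")
  unlink(c(out1, out2), recursive = TRUE)
  runScenario(syntheticConfig(out1), verbose = FALSE)
  runScenario(syntheticConfig(out2), verbose = FALSE)
  for (f in list.files(out1)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("path GeoJSON round-trips coordinates and properties", {
  land <- generateLandscape(landscapeParams(seed = 7))
  slope <- computeSlope(land$dem)
  cost <- buildCostSurface(slope, scenarioMask(land$dem, land$scenario),
                           scenarioName = land$scenario@name)
  p <- leastCostPath(cost, c(43.5, 35.5), c(79.3, 35.5),
                     startName = "SouthwestCave", endName = "EastCave",
                     scenarioName = land$scenario@name)
  f <- tempfile(fileext = ".geojson")
  writePathGeoJSON(p, f)
  back <- readPathGeoJSON(f)
  expect_equal(unname(back$coords), unname(p@coords))
  expect_equal(back$properties$total_cost, p@totalCost)
  expect_identical(back$properties$scenario, "MIS4-Atelian")
})

test_that("scenario YAML and polygon GeoJSON round-trip", {
  land <- generateLandscape(landscapeParams(seed = 7))
  sc <- land$scenario
  f <- file.path(tempdir(), "scenario.yaml")
  writeScenario(sc, f)
  sc2 <- readScenario(f)
  expect_identical(sc2@name, sc@name)
  expect_equal(sc2@seaLevel, sc@seaLevel)
  expect_equal(sc2@seaSeed, sc@seaSeed)
  expect_identical(length(sc2@barrierPolygons), length(sc@barrierPolygons))
  for (i in seq_along(sc@barrierPolygons)) {
    a <- closeRingForTest(sc@barrierPolygons[[i]])
    expect_equal(unname(sc2@barrierPolygons[[i]]), unname(a))
  }
  # masks built from the round-tripped scenario are identical
  m1 <- scenarioMask(land$dem, sc)
  m2 <- scenarioMask(land$dem, sc2)
  expect_identical(blockedCells(m1), blockedCells(m2))
})

test_that("run configs read from YAML resolve relative paths", {
  dir <- file.path(tempdir(), "cfgdir")
  dir.create(dir, showWarnings = FALSE)
  land <- generateLandscape(landscapeParams(seed = 7))
  writeGrid(land$dem, file.path(dir, "dem.asc"))
  writeSites(land$sites, file.path(dir, "sites.csv"))
  writeScenario(land$scenario, file.path(dir, "scenario.yaml"))
  cfgFile <- file.path(dir, "run.yaml")
  yaml::write_yaml(list(dem = "dem.asc", sites = "sites.csv",
                        scenario = "scenario.yaml",
                        routes = list(list(start = "SouthwestCave",
                                           end = "EastCave")),
                        out_dir = file.path(dir, "out")), cfgFile)
  mf <- runScenario(cfgFile, verbose = FALSE)
  expect_identical(length(mf$routes), 1L)
  expect_true(is.finite(mf$routes[[1]]$total_cost))
  expect_identical(length(mf$inputs), 3L) # md5 of each input file
})
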