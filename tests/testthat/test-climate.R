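constGrid <- function(value, nr = 5, nc = 5, cs = 0.5)
  toyGrid(matrix(value, nr, nc), cellSize = cs, xOrigin = 10, yOrigin = 45)

test_that("temporal rate is |dT|/dt with nodata propagation", {
  pair <- climateEpochPair(constGrid(10), constGrid(10), 1e5)
  expect_true(all(gridValues(temporalRate(pair)) == 0))
  pair2 <- climateEpochPair(constGrid(15), constGrid(10), 1e5)
  expect_true(all(gridValues(temporalRate(pair2)) == 5e-5))
  told <- constGrid(15); v <- gridValues(told); v[2, 2] <- NA
  gridValues(told) <- v
  r <- gridValues(temporalRate(climateEpochPair(told, constGrid(10), 1e5)))
  expect_true(is.na(r[2, 2]) && sum(is.na(r)) == 1L)
  expect_error(climateEpochPair(constGrid(1), constGrid(1, nr = 4), 1e5))
})

test_that("spatial gradient recovers linear fields and is isotropic", {
  expect_true(all(gridValues(spatialGradient(constGrid(12)))[2:4, 2:4] == 0))
  # 0.0065 degC per meter northward -> 6.5 degC/km
  nr <- 7; nc <- 7; cs <- 0.01
  g <- toyGrid(matrix(0, nr, nc), cellSize = cs, xOrigin = 0, yOrigin = 0)
  latM <- (cellCenters(g)$lat) * 111320 # meters northward of the equator line
  north <- toyGrid(matrix(0.0065 * latM, nr, nc), cellSize = cs,
                   xOrigin = 0, yOrigin = 0)
  gn <- gridValues(spatialGradient(north))[2:6, 2:6]
  expect_equal(max(abs(gn - 6.5)), 0, tolerance = 1e-9)
  # same magnitude for an eastward field at the equator
  lonM <- (cellCenters(g)$lon) * 111320 # cos(lat ~ 0) ~ 1
  east <- toyGrid(matrix(0.0065 * lonM, nr, nc, byrow = TRUE), cellSize = cs,
                  xOrigin = 0, yOrigin = 0)
  ge <- gridValues(spatialGradient(east))[2:6, 2:6]
  expect_equal(max(abs(ge - 6.5)), 0, tolerance = 1e-3)
})

test_that("velocity reproduces the closed form and caps flat fields", {
  # 5 degC over 100 kyr across a 5 degC/km gradient -> 0.001 km/century
  nr <- 7; nc <- 7; cs <- 0.01
  latM <- -(seq_len(nr) - 0.5) * cs * 111320
  tOld <- toyGrid(matrix(rep(5e-3 * latM, nc), nr, nc), cellSize = cs,
                  xOrigin = 0, yOrigin = 0)
  tNew <- toyGrid(gridValues(tOld) - 5, cellSize = cs, xOrigin = 0, yOrigin = 0)
  pair <- climateEpochPair(tOld, tNew, 1e5)
  v <- gridValues(climateVelocity(pair))[2:6, 2:6]
  expect_equal(max(abs(v - 0.001)), 0, tolerance = 1e-9)
  # identical epochs -> zero velocity
  v0 <- gridValues(climateVelocity(climateEpochPair(tOld, tOld, 1e5)))[2:6, 2:6]
  expect_true(all(v0 == 0))
  # spatially constant field with nonzero cooling -> capped
  flat <- climateEpochPair(constGrid(10), constGrid(5), 1e5)
  vf <- climateVelocity(flat, vCap = 10000)
  expect_true(all(gridValues(vf)[2:4, 2:4] == 10000))
  expect_error(climateVelocity(pair, vCap = 0), class = "pcParameterError")
})

test_that("doubling the epoch separation halves uncapped velocity", {
  nr <- 9; nc <- 9; cs <- 0.01
  latM <- -(seq_len(nr) - 0.5) * cs * 111320
  tOld <- toyGrid(matrix(rep(4e-3 * latM, nc), nr, nc), cellSize = cs)
  tNew <- toyGrid(gridValues(tOld) - 3, cellSize = cs)
  v1 <- gridValues(climateVelocity(climateEpochPair(tOld, tNew, 1e5)))
  v2 <- gridValues(climateVelocity(climateEpochPair(tOld, tNew, 2e5)))
  keep <- !is.na(v1)
  expect_equal(v2[keep], v1[keep] / 2, tolerance = 1e-12)
})

test_that("stability mask counts follow the inclusive rank policy", {
  nr <- 10; nc <- 10
  vg <- new("VelocityGrid", toyGrid(matrix(sample(1:100), nr, nc)),
            vCap = 10000)
  m <- stabilityMask(vg, 0.25)
  stable <- !blockedCells(m)
  expect_identical(sum(stable), 25L)
  expect_true(all(sort(gridValues(vg)[stable]) == 1:25))
  same <- new("VelocityGrid", toyGrid(matrix(7, 4, 4)), vCap = 10)
  expect_identical(sum(!blockedCells(stabilityMask(same, 0.5))), 16L)
  half <- new("VelocityGrid", toyGrid(matrix(rep(c(0, 10000), 50), 10, 10)),
              vCap = 10000)
  mh <- stabilityMask(half, 0.5)
  expect_true(all(gridValues(half)[!blockedCells(mh)] == 0))
  expect_identical(sum(!blockedCells(mh)), 50L)
  expect_error(stabilityMask(vg, 1.2), class = "pcParameterError")
  allNA <- new("VelocityGrid", toyGrid(matrix(NA_real_, 3, 3)), vCap = 1)
  expect_error(stabilityMask(allNA, 0.5), class = "pcEmptyInputError")
})

test_that("velocity is lowest where terrain is steepest (mountain refugia)", {
  land <- generateLandscape(landscapeParams(seed = 7))
  pair <- generateClimate(land$dem, epochalCooling = 5, noiseSd = 0)
  v <- gridValues(climateVelocity(pair))
  s <- gridValues(computeSlope(land$dem))
  keep <- !is.na(v) & !is.na(s) & s > 0
  rho <- cor(s[keep], v[keep], method = "spearman")
  expect_lt(rho, 0)
})

test_that("grid summaries reduce over region masks", {
  set.seed(2)
  vals <- matrix(runif(36, 0, 10), 6, 6)
  g <- toyGrid(vals)
  sm <- gridSummary(g)
  expect_equal(sm$min, min(vals)); expect_equal(sm$max, max(vals))
  region <- elevationBandMask(g, 5, Inf) # open cells: values >= 5
  smr <- gridSummary(g, region)
  expect_equal(smr$min, min(vals[vals >= 5]))
  expect_identical(smr$n, sum(vals >= 5))
})
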