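openMask <- function(g) elevationBandMask(g, -Inf, Inf)

test_that("cost surface is linear in slope with Inf at barriers", {
  s <- flatSlope(4, 4)
  expect_true(all(gridValues(buildCostSurface(s, openMask(s), 0.5)) == 1))
  s30 <- flatSlope(4, 4, 30)
  expect_true(all(gridValues(buildCostSurface(s30, openMask(s30), 1.0)) == 31))
  # a desert-blocked cell is non-traversable regardless of slope
  z <- matrix(0, 4, 4); z[2, 2] <- 1
  blocked <- combineMasks(list(openMask(s), local({
    m <- openMask(s); m@values <- z; m
  })))
  cs <- buildCostSurface(s, blocked, 0.1)
  expect_identical(gridValues(cs)[2, 2], Inf)
  expect_error(buildCostSurface(s, openMask(s), -1), class = "pcParameterError")
  expect_error(buildCostSurface(s, openMask(flatSlope(3, 3))),
               class = "pcAlignmentError")
})

test_that("tobler cost is 1 on flat ground and grows with slope", {
  s <- flatSlope(3, 3, 0)
  expect_true(all(gridValues(buildCostSurface(s, openMask(s),
                                              costFunction = "tobler")) == 1))
  c10 <- gridValues(buildCostSurface(flatSlope(3, 3, 10),
                                     openMask(s), costFunction = "tobler"))[1, 1]
  expect_equal(c10, exp(3.5 * tan(10 * pi / 180)))
})

test_that("simple lattice paths have exact analytic costs", {
  strip <- buildCostSurface(flatSlope(1, 5), openMask(flatSlope(1, 5)), 0)
  p <- leastCostPath(strip, cellCenters(strip, 1, 1),
                     cellCenters(strip, 1, 5), distance = "unit")
  expect_identical(nrow(p@cells), 5L)
  expect_equal(p@totalCost, 4)
  sq <- buildCostSurface(flatSlope(3, 3), openMask(flatSlope(3, 3)), 0)
  pd <- leastCostPath(sq, cellCenters(sq, 1, 1), cellCenters(sq, 3, 3),
                      distance = "unit")
  expect_identical(nrow(pd@cells), 3L)
  expect_equal(pd@totalCost, 2 * sqrt(2))
})

test_that("Dijkstra matches exhaustive Bellman-Ford on seeded 7x7 grids", {
  for (seed in c(42, 1:9)) {
    set.seed(seed)
    cost <- matrix(runif(49, 1, 10), 7, 7)
    g <- toyGrid(cost, cellSize = 0.5, xOrigin = 10, yOrigin = 45)
    cs <- buildCostSurface(g, openMask(g), 0) # slope 0 -> then overwrite
    cs@values <- cost
    p <- leastCostPath(cs, cellCenters(cs, 1, 1), cellCenters(cs, 7, 7),
                       distance = "unit")
    expect_equal(p@totalCost, bellmanFordCost(cost, c(1, 1), c(7, 7)),
                 tolerance = 1e-12, info = sprintf("seed %d", seed))
    # great-circle distances agree with the oracle too
    pg <- leastCostPath(cs, cellCenters(cs, 1, 1), cellCenters(cs, 7, 7))
    expect_equal(pg@totalCost,
                 bellmanFordCost(cost, c(1, 1), c(7, 7), grid = cs,
                                 unitDistance = FALSE),
                 tolerance = 1e-9, info = sprintf("seed %d gc", seed))
  }
})

test_that("route cost is symmetric in direction", {
  set.seed(11)
  cost <- matrix(runif(64, 1, 5), 8, 8)
  g <- toyGrid(cost, cellSize = 0.3, xOrigin = 0, yOrigin = 40)
  cs <- buildCostSurface(g, openMask(g), 0); cs@values <- cost
  a <- leastCostPath(cs, cellCenters(cs, 1, 2), cellCenters(cs, 8, 7))
  b <- leastCostPath(cs, cellCenters(cs, 8, 7), cellCenters(cs, 1, 2))
  expect_equal(a@totalCost, b@totalCost, tolerance = 1e-12)
  expect_equal(a@lengthKm, b@lengthKm, tolerance = 1e-9)
})

test_that("blocking cells never lowers cost and a full cut is unreachable", {
  set.seed(3)
  cost <- matrix(runif(81, 1, 4), 9, 9)
  g <- toyGrid(cost, cellSize = 0.2, xOrigin = 0, yOrigin = 40)
  base <- buildCostSurface(g, openMask(g), 0); base@values <- cost
  p0 <- leastCostPath(base, cellCenters(base, 1, 1), cellCenters(base, 9, 9),
                      distance = "unit")
  for (i in 1:10) {
    r <- sample(2:8, 1); c <- sample(2:8, 1)
    cut <- base; cut@values[r, c] <- Inf
    p1 <- leastCostPath(cut, cellCenters(cut, 1, 1), cellCenters(cut, 9, 9),
                        distance = "unit")
    expect_gte(p1@totalCost, p0@totalCost - 1e-12)
  }
  sever <- base; sever@values[, 5] <- Inf
  expect_error(leastCostPath(sever, cellCenters(sever, 1, 1),
                             cellCenters(sever, 9, 9)),
               class = "pcUnreachableError")
})

test_that("endpoints on blocked cells fail loudly naming the cell", {
  g <- flatSlope(5, 5)
  cs <- buildCostSurface(g, openMask(g), 0)
  cs@values[3, 3] <- Inf
  expect_error(leastCostPath(cs, cellCenters(cs, 3, 3), cellCenters(cs, 1, 1)),
               "\\(3, 3\\)", class = "pcPlacementError")
  expect_error(leastCostPath(cs, c(500, 0), cellCenters(cs, 1, 1)),
               class = "pcPlacementError")
})

test_that("path length follows the haversine closed form", {
  expect_equal(haversineKm(0, 0, 1, 0), 111.1951, tolerance = 1e-4)
  expect_equal(pathLengthKm(rbind(c(0, 0), c(1, 0))), 111.1951,
               tolerance = 1e-4)
  expect_equal(pathLengthKm(rbind(c(10, 45))), 0)
  loop <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(pathLengthKm(loop), pathLengthKm(loop[5:1, ]))
})

test_that("uniform-cost routes stay within the 8-connected elongation bound", {
  g <- flatSlope(30, 30, 0, cellSize = 0.1)
  cs <- buildCostSurface(g, openMask(g), 0)
  start <- cellCenters(cs, 25, 3); end <- cellCenters(cs, 4, 28)
  p <- leastCostPath(cs, start, end)
  straight <- haversineKm(start[1], start[2], end[1], end[2])
  expect_lt(p@lengthKm / straight, 1.085)
})

test_that("identical tied grids give byte-identical deterministic paths", {
  cost <- matrix(1, 10, 10) # everything tied
  g <- toyGrid(cost, cellSize = 0.2, xOrigin = 0, yOrigin = 40)
  cs <- buildCostSurface(g, openMask(g), 0)
  p1 <- leastCostPath(cs, cellCenters(cs, 1, 1), cellCenters(cs, 10, 4))
  p2 <- leastCostPath(cs, cellCenters(cs, 1, 1), cellCenters(cs, 10, 4))
  expect_identical(p1@cells, p2@cells)
})
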