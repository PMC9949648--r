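# Small grids built in code; all fixtures are generated at test time.

toyGrid <- function(values, cellSize = 1, xOrigin = 0, yOrigin = 0) {
  GeoGrid(values, xOrigin = xOrigin, yOrigin = yOrigin, cellSize = cellSize)
}

randomGrid <- function(seed, nr = 5, nc = 5, min = 0, max = 100,
                       cellSize = 0.5) {
  set.seed(seed)
  toyGrid(matrix(runif(nr * nc, min, max), nr, nc), cellSize = cellSize,
          xOrigin = 10, yOrigin = 45)
}

# 5x5 toy basin: 3x3 bowl at -100 m in a +200 m rim, optional isolated pit.
toyBasin <- function(pit = FALSE) {
  z <- matrix(200, 5, 5)
  z[2:4, 2:4] <- -100
  if (pit) z[5, 5] <- -100 # corner pit, not 4-connected to the bowl
  toyGrid(z)
}

# planar inclined plane in unit-cell mode: z = gx * col + gy * row
planeGrid <- function(gx, gy, nr = 9, nc = 9) {
  toyGrid(outer(seq_len(nr), seq_len(nc), function(r, c) gx * c + gy * r))
}

emptyMask <- function(grid) {
  paleocorridor::combineMasks(list(paleocorridor::elevationBandMask(
    grid, -Inf, Inf)))
}

flatSlope <- function(nr, nc, value = 0, cellSize = 0.5) {
  toyGrid(matrix(value, nr, nc), cellSize = cellSize, xOrigin = 10,
          yOrigin = 45)
}
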