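test_that("ASCII grid read honors header and identity values", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 10", "yllcorner 40",
               "cellsize 0.5", "NODATA_value -9999",
               "100 100 100", "100 100 100", "100 100 100"), f)
  g <- readGrid(f)
  expect_identical(dim(g), c(3L, 3L))
  expect_true(all(gridValues(g) == 100))
  expect_equal(unname(gridOrigin(g)), c(10, 41.5)) # NW corner from ll corner
  expect_equal(cellSize(g), 0.5)
})

test_that("malformed ASCII headers raise format errors naming the field", {
  f <- tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 0", "NODATA_value -9999", "1 1 1", "1 1 1", "1 1 1"), f)
  expect_error(readGrid(f), "cellsize", class = "pcFormatError")
  writeLines(c("ncols 3", "nrows 3", "yllcorner 0",
               "cellsize 1", "1 1 1", "1 1 1", "1 1 1"), f)
  expect_error(readGrid(f), "xllcorner", class = "pcFormatError")
  writeLines(c("ncols 3", "nrows 3", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "1 1", "1 1 1"), f)
  expect_error(readGrid(f), "expected", class = "pcFormatError")
})

test_that("round trips preserve values, georeference and nodata count", {
  for (seed in 1:50) {
    g <- randomGrid(seed)
    v <- gridValues(g)
    v[] <- signif(v, 6) # the documented ASCII precision boundary
    if (seed %% 3 == 0) v[seed %% 5 + 1, 3] <- NA
    gridValues(g) <- v
    for (ext in c(".asc", ".tif")) {
      f <- tempfile(fileext = ext)
      writeGrid(g, f)
      g2 <- readGrid(f)
      expect_equal(gridValues(g2), gridValues(g), tolerance = 0,
                   info = sprintf("seed %d dialect %s", seed, ext))
      expect_identical(sum(is.na(gridValues(g2))), sum(is.na(gridValues(g))))
      expect_true(sameGeometry(g, g2))
    }
  }
})

test_that("ASCII writing is bit-stable after the first 6-digit round trip", {
  g <- randomGrid(99)
  f1 <- tempfile(fileext = ".asc"); f2 <- tempfile(fileext = ".asc")
  writeGrid(g, f1)
  g1 <- readGrid(f1)
  expect_equal(gridValues(g1), gridValues(g), tolerance = 1e-5)
  writeGrid(g1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("writing to an unwritable location raises an I/O error", {
  suppressWarnings({ # file() warns about the missing directory first
    expect_error(writeGrid(randomGrid(1), "/no/such/dir/grid.asc"),
                 class = "pcIOError")
    expect_error(writeGrid(randomGrid(1), "/no/such/dir/grid.tif"),
                 class = "pcIOError")
  })
})

test_that("the GeoTIFF dialect agrees with an independent TIFF reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  g <- randomGrid(42, nr = 7, nc = 9)
  v <- gridValues(g); v[3, 4] <- NA; gridValues(g) <- v
  f <- tempfile(fileext = ".tif")
  writeGrid(g, f)
  out <- tempfile(fileext = ".txt")
  code <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread('%s').astype(float)\n",
    "np.savetxt('%s', a)\n"), f, out)
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  res <- system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(out))
  a <- as.matrix(read.table(out))
  dimnames(a) <- NULL
  a[a == nodataValue(g)] <- NA
  expect_equal(a, gridValues(g), tolerance = 0)
})

test_that("alignTo is the identity on shared geometry and idempotent", {
  g <- randomGrid(5)
  for (m in c("nearest", "bilinear")) {
    expect_equal(gridValues(alignTo(g, g, m)), gridValues(g))
    once <- alignTo(g, g, m)
    expect_equal(gridValues(alignTo(g, once, m)), gridValues(once))
  }
  const <- toyGrid(matrix(7, 6, 6), cellSize = 0.4, xOrigin = 9.9,
                   yOrigin = 45.1)
  for (m in c("nearest", "bilinear")) {
    al <- alignTo(g, const, m)
    expect_true(all(gridValues(al)[!is.na(gridValues(al))] == 7))
  }
})

test_that("bilinear upsampling matches the hand-computed oracle", {
  src <- toyGrid(matrix(c(0, 2, 1, 3), 2, 2), cellSize = 1) # rows x cols
  ref <- toyGrid(matrix(0, 4, 4), cellSize = 0.5)
  out <- gridValues(alignTo(ref, src, "bilinear"))
  for (r in 1:4) for (c in 1:4) {
    fr <- (r - 0.5) / 2 - 0.5; fc <- (c - 0.5) / 2 - 0.5
    expected <- if (fr < 0 || fc < 0 || fr > 1 || fc > 1) NA_real_ else
      bilinearAt(gridValues(src), fr, fc)
    expect_equal(out[r, c], expected, info = sprintf("cell %d %d", r, c))
  }
})

test_that("disjoint extents raise an alignment error", {
  a <- toyGrid(matrix(1, 4, 4), cellSize = 1, xOrigin = 0, yOrigin = 10)
  b <- toyGrid(matrix(1, 4, 4), cellSize = 1, xOrigin = 100, yOrigin = 10)
  expect_error(alignTo(a, b), class = "pcAlignmentError")
})
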