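test_that("ASCII grid write/read round trip is bit-exact, including no-data", {
  set.seed(11)
  g <- matrix(runif(20 * 15, -100, 100), 20, 15)
  g[sample.int(300, 12)] <- NA_real_
  g[1, 1] <- 1 / 3                      # needs 17 significant digits
  lay <- makeLayer(g, "precip", xll = -120.25, yll = 33.5, cs = 0.25)
  f <- tempfile(fileext = ".asc")
  writeAsciiGrid(lay, f)
  back <- readAsciiGrid(f, "precip")
  expect_identical(gridValues(back), g)
  expect_identical(c(back@xll, back@yll, back@cellsize),
                   c(-120.25, 33.5, 0.25))
})

test_that("scenario manifest round trip preserves values and metadata", {
  set.seed(12)
  vars <- c("temp", "precip", "temp_sd", "temp_cool")
  sc <- randomScenario(8, 10, vars, seed = 12, xll = -5, yll = 40,
                       cs = 0.5, naFrac = 0.1)
  sc@name <- "present"
  d <- tempfile()
  writeScenario(sc, d)
  back <- readScenario(file.path(d, "manifest.yml"))
  expect_identical(variableNames(back), vars)
  expect_equal(scenarioAge(back), 0)
  expect_identical(scenarioName(back), "present")
  for (v in vars)
    expect_identical(gridValues(getLayer(back, v)),
                     gridValues(getLayer(sc, v)))
})

test_that("co-registration violations and duplicate variables are rejected", {
  a <- makeLayer(matrix(1, 4, 4), "a")
  bBad <- makeLayer(matrix(1, 5, 4), "b")
  expect_error(climateScenario("s", 0, list(a, bBad)), "co-registered")
  bShift <- climateLayer("b", matrix(1, 4, 4), xll = 1, yll = 0,
                         cellsize = 1)
  expect_error(climateScenario("s", 0, list(a, bShift)), "co-registered")
  a2 <- makeLayer(matrix(2, 4, 4), "a")
  expect_error(climateScenario("s", 0, list(a, a2)), "duplicate")
})

test_that("points sample the containing cell; cell centers are exact", {
  g1 <- matrix(as.numeric(1:12), 3, 4)      # 3 rows x 4 cols
  g2 <- g1 * 10
  sc <- makeScenario(list(v1 = g1, v2 = g2), xll = 0, yll = 0, cs = 1)
  ## center of cell (row 2, col 3): lon 2.5, lat = 3 - 1.5 = 1.5
  sv <- sampleValues(sc, cbind(2.5, 1.5))
  expect_true(sv$valid)
  expect_equal(c(sv$row, sv$col), c(2, 3))
  expect_equal(sv$v1, g1[2, 3])
  expect_equal(sv$v2, g2[2, 3])
})

test_that("boundary points land in exactly one cell (half-open convention)", {
  nr <- 4; nc <- 5; cs <- 1
  g <- matrix(0, nr, nc)
  sc <- makeScenario(list(v = g), xll = 0, yll = 0, cs = cs)
  ## brute-force containment oracle over all cells
  containCount <- function(lon, lat) {
    cnt <- 0
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      xlo <- (c - 1) * cs; xhi <- c * cs
      yhi <- nr * cs - (r - 1) * cs; ylo <- yhi - cs
      if (lon >= xlo && lon < xhi && lat > ylo && lat <= yhi)
        cnt <- cnt + 1
    }
    cnt
  }
  pts <- rbind(c(2, 2), c(2, 4), c(0, 4), c(2.5, 3), c(1, 1))  # edges/corners
  sv <- sampleValues(sc, pts)
  for (i in seq_len(nrow(pts))) {
    expect_equal(containCount(pts[i, 1], pts[i, 2]), 1L)
    expect_true(sv$valid[i])
  }
  ## interior boundary lon 2 must belong to the cell to its east (col 3)
  expect_equal(sv$col[1], 3)
  ## north edge belongs to row 1; east/south edges are outside
  expect_equal(sv$row[3], 1)
  out <- sampleValues(sc, rbind(c(5, 2), c(2, 0)))
  expect_false(any(out$valid))
})

test_that("no-data cells flag points invalid without dropping them", {
  g <- matrix(1, 3, 3); g[2, 2] <- NA
  sc <- makeScenario(list(v = g, w = matrix(2, 3, 3)))
  sv <- sampleValues(sc, rbind(c(1.5, 1.5), c(0.5, 0.5)))
  expect_equal(nrow(sv), 2L)
  expect_false(sv$valid[1])              # ocean/no-data cell
  expect_true(is.na(sv$v[1]) && is.na(sv$w[1]))
  expect_true(sv$valid[2])
})

test_that("sampleValues is permutation-equivariant and layer-order invariant", {
  sc <- randomScenario(6, 6, c("a", "b", "c"), seed = 3, naFrac = 0.1)
  set.seed(4)
  pts <- cbind(runif(25, -1, 7), runif(25, -1, 7))
  sv <- sampleValues(sc, pts)
  perm <- sample.int(25)
  svP <- sampleValues(sc, pts[perm, ])
  expect_equal(svP, sv[perm, ], ignore_attr = TRUE)
  scR <- climateScenario("r", 0, rev(sc@layers))
  svR <- sampleValues(scR, pts)
  expect_equal(svR[c("a", "b", "c", "valid")], sv[c("a", "b", "c", "valid")])
})

test_that("cleaning removes duplicates and invalid points, and is idempotent", {
  g <- matrix(1, 4, 4); g[1, 1] <- NA   # an "ocean" cell in the north-west
  sc <- makeScenario(list(v = g))
  lon <- c(1.5, 1.5, 2.5, 0.5, 0.5, 9.0, 2.2)
  lat <- c(1.5, 1.5, 2.5, 3.5, 3.5, 1.0, 0.7)
  ## duplicates: one exact pair (1.5,1.5) and one exact ocean pair (0.5,3.5)
  ## invalid: remaining (0.5,3.5) is the NA cell; (9,1) is off-grid
  occ <- occurrenceSet("sp", lon, lat)
  out <- cleanOccurrences(occ, sc)
  expect_equal(out$report$n_input, 7L)
  expect_equal(out$report$n_duplicate, 2L)
  expect_equal(out$report$n_invalid, 2L)
  expect_equal(nOccurrences(out$occurrences), 3L)
  ## counting oracle: size reduced by duplicates + invalid
  expect_equal(nOccurrences(out$occurrences),
               out$report$n_input - out$report$n_duplicate -
                 out$report$n_invalid)
  again <- cleanOccurrences(out$occurrences, sc)
  expect_identical(occurrenceCoords(again$occurrences),
                   occurrenceCoords(out$occurrences))
  expect_equal(again$report$n_duplicate + again$report$n_invalid, 0L)
})

test_that("cleaning passes through an already-clean set and allows empty results", {
  sc <- makeScenario(list(v = matrix(1, 2, 2)))
  occ <- occurrenceSet("sp", c(0.5, 1.5), c(0.5, 1.5))
  out <- cleanOccurrences(occ, sc)
  expect_identical(occurrenceCoords(out$occurrences), occurrenceCoords(occ))
  allBad <- occurrenceSet("sp", c(30, 40), c(30, 40))
  outBad <- cleanOccurrences(allBad, sc)
  expect_equal(nOccurrences(outBad$occurrences), 0L)
})

test_that("occurrence CSV round trip preserves species and coordinates", {
  occs <- list(a = occurrenceSet("a", c(1, 2), c(3, 4), source = "gbif"),
               b = occurrenceSet("b", 5, 6))
  f <- tempfile(fileext = ".csv")
  writeOccurrences(occs, f)
  back <- readOccurrences(f)
  expect_named(back, c("a", "b"))
  expect_equal(occurrenceCoords(back$a), occurrenceCoords(occs$a),
               ignore_attr = TRUE)
  expect_equal(back$a@source, "gbif")
})
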