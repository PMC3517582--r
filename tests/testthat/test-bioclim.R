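test_that("fitted bounds are the observed extremes; degenerate envelopes allowed", {
  tab <- data.frame(lon = 1:3, lat = 1:3, row = 1L, col = 1:3,
                    valid = TRUE, v = c(2, 5, 3))
  env <- fitEnvelope(tab, "sp", warnBelow = 0)
  expect_equal(envelopeBounds(env),
               data.frame(variable = "v", min = 2, max = 5))
  expect_equal(nPoints(env), 3L)
  ## all points in one climate cell -> min == max, as for single-niche
  ## narrow endemics
  tab1 <- data.frame(lon = 1, lat = 1, row = 1L, col = 1L, valid = TRUE,
                     v = 9.9)
  expect_warning(env1 <- fitEnvelope(tab1, "endemic"), "1 point")
  expect_equal(env1@mins, env1@maxs)
  expect_error(fitEnvelope(tab1[0, ], "none"), "no valid points")
})

test_that("fitted bounds equal a direct column scan on random tables", {
  set.seed(21)
  for (trial in 1:5) {
    n <- 100
    tab <- data.frame(lon = runif(n), lat = runif(n), row = 1L, col = 1L,
                      valid = sample(c(TRUE, FALSE), n, TRUE, c(.8, .2)),
                      a = rnorm(n), b = runif(n, -50, 50))
    env <- fitEnvelope(tab, "sp")
    keep <- tab$valid
    expect_equal(env@mins, c(min(tab$a[keep]), min(tab$b[keep])))
    expect_equal(env@maxs, c(max(tab$a[keep]), max(tab$b[keep])))
  }
})

test_that("projection equals the per-cell counting oracle (L = 1, 2, 4)", {
  for (L in c(1, 2, 4)) {
    vars <- paste0("v", seq_len(L))
    sc <- randomScenario(12, 9, vars, seed = 30 + L, naFrac = 0.08)
    set.seed(40 + L)
    env <- envelopeModel("sp", vars, mins = runif(L, -8, 0),
                         maxs = runif(L, 0, 8))
    surf <- projectEnvelope(env, sc)
    expect_equal(gridValues(surf), projectionOracle(env, sc))
    expect_equal(nLayers(surf), L)
  }
})

test_that("surface values are multiples of 1/L and mean equals mean inside-fraction", {
  vars <- c("a", "b", "c")
  sc <- randomScenario(10, 10, vars, seed = 51)
  env <- envelopeModel("sp", vars, mins = c(-5, -2, 0), maxs = c(5, 9, 1))
  surf <- projectEnvelope(env, sc)
  v <- gridValues(surf)
  expect_true(all(abs(v * 3 - round(v * 3)) < 1e-12))
  insideFrac <- vapply(seq_along(vars), function(i) {
    g <- gridValues(getLayer(sc, vars[i]))
    mean(g >= env@mins[i] & g <= env@maxs[i])
  }, numeric(1))
  expect_equal(mean(v), mean(insideFrac))
})

test_that("widening any bound never decreases suitability anywhere", {
  vars <- c("a", "b")
  sc <- randomScenario(8, 8, vars, seed = 61)
  env <- envelopeModel("sp", vars, mins = c(-3, -1), maxs = c(3, 2))
  base <- gridValues(projectEnvelope(env, sc))
  for (j in 1:2) {
    wide <- env
    wide@mins[j] <- wide@mins[j] - 5
    wide@maxs[j] <- wide@maxs[j] + 5
    expect_true(all(gridValues(projectEnvelope(wide, sc)) >= base))
  }
})

test_that("an envelope scores all its own training cells fully suitable", {
  sc <- randomScenario(15, 15, c("a", "b", "c", "d"), seed = 71)
  set.seed(72)
  pts <- cbind(runif(40, 0, 15), runif(40, 0, 15))
  sv <- sampleValues(sc, pts)
  env <- fitEnvelope(sv, "sp")
  surf <- projectEnvelope(env, sc)
  cells <- cbind(sv$row[sv$valid], sv$col[sv$valid])
  expect_true(all(gridValues(surf)[cells] == 1))
})

test_that("projection requires every model variable in the scenario", {
  sc <- randomScenario(4, 4, "a", seed = 81)
  env <- envelopeModel("sp", c("a", "zz"), c(0, 0), c(1, 1))
  expect_error(projectEnvelope(env, sc), "zz")
})

test_that("classification separates full, all-but-one and below", {
  g <- matrix(c(1, 0.75, 0.5, 0.25, 0, NA), 2, 3)
  surf <- new("SuitabilitySurface", grid = g, nLayers = 4L,
              xll = 0, yll = 0, cellsize = 1)
  cls <- classifySurface(surf)
  expect_equal(as.vector(cls), c(2L, 1L, 0L, 0L, 0L, NA))
  ## single-variable model: only full/below occur
  s1 <- new("SuitabilitySurface", grid = matrix(c(0, 1), 1, 2),
            nLayers = 1L, xll = 0, yll = 0, cellsize = 1)
  expect_equal(as.vector(classifySurface(s1)), c(0L, 2L))
})

test_that("environmentally unique points are distinct climate vectors", {
  tab <- data.frame(lon = 1:6, lat = 1, row = 1L, col = 1L,
                    valid = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
                    a = c(1, 1, 2, 2, 1, 9), b = c(5, 5, 5, 6, 5, 9))
  expect_equal(countEnvUnique(tab), 3L)    # (1,5), (2,5), (2,6)
  one <- data.frame(lon = 1:4, lat = 1, row = 1L, col = 1L, valid = TRUE,
                    a = 2, b = 3)
  expect_equal(countEnvUnique(one), 1L)    # all points in one climate cell
  expect_equal(countEnvUnique(tab[tab$valid == FALSE, ]), 0L)
})

test_that("unique count equals a brute-force distinct-row scan on random data", {
  set.seed(91)
  for (trial in 1:5) {
    n <- 60
    tab <- data.frame(lon = runif(n), lat = runif(n), row = 1L, col = 1L,
                      valid = runif(n) < 0.9,
                      a = sample(1:4, n, TRUE) + 0.5,
                      b = sample(1:3, n, TRUE) / 7)
    keep <- tab[tab$valid, c("a", "b")]
    oracle <- nrow(unique(keep))
    expect_equal(countEnvUnique(tab), oracle)
  }
})

test_that("envelope CSV round trip preserves bounds and counts", {
  envs <- list(x = envelopeModel("x", c("a", "b"), c(0, -1), c(2, 5), 7L),
               y = envelopeModel("y", c("a", "b"), c(1, 1), c(1, 2)))
  f <- tempfile(fileext = ".csv")
  writeEnvelopes(envs, f)
  back <- readEnvelopes(f)
  expect_equal(envelopeBounds(back$x), envelopeBounds(envs$x))
  expect_equal(nPoints(back$x), 7L)
  expect_true(is.na(nPoints(back$y)))
})
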