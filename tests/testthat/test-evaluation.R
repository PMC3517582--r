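test_that("AUC endpoints behave as advertised: perfect = 1, all ties = 0.5", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.2, 0.1)), 1.0)
  expect_equal(aucScore(rep(0.5, 4), rep(0.5, 6)), 0.5)
  expect_equal(aucScore(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_error(aucScore(numeric(0), 1), "non-empty")
})

test_that("rank AUC equals exhaustive pair enumeration, with ties", {
  set.seed(101)
  for (trial in 1:20) {
    p <- sample(seq(0, 1, by = 0.25), sample(2:12, 1), replace = TRUE)
    b <- sample(seq(0, 1, by = 0.25), sample(2:20, 1), replace = TRUE)
    expect_equal(aucScore(p, b), aucOracle(p, b))
  }
})

test_that("AUC complement and monotone-transform invariance hold", {
  set.seed(102)
  p <- runif(15); b <- runif(25)     # tie-free almost surely
  expect_equal(aucScore(p, b) + aucScore(b, p), 1)
  expect_equal(aucScore(exp(3 * p) + 1, exp(3 * b) + 1), aucScore(p, b))
})

test_that("background sampling is seeded, uniform and exclusion-aware", {
  sc <- randomScenario(10, 10, "v", seed = 111, naFrac = 0.1)
  bg1 <- sampleBackground(sc, excludeCells = 1:5, n = 30, seed = 9)
  bg2 <- sampleBackground(sc, excludeCells = 1:5, n = 30, seed = 9)
  expect_identical(bg1, bg2)
  expect_false(any(bg1$cell %in% 1:5))
  ok <- which(!is.na(gridValues(getLayer(sc, "v"))))
  expect_true(all(bg1$cell %in% ok))
  ## excluding everything yields an empty sample with a warning
  expect_warning(empty <- sampleBackground(sc, excludeCells = ok, n = 5,
                                           seed = 1), "eligible")
  expect_equal(nrow(empty), 0L)
})

test_that("single-cell background draws are near-uniform over eligible cells", {
  sc <- makeScenario(list(v = matrix(1, 5, 5)))
  draws <- vapply(1:4000, function(i)
    sampleBackground(sc, n = 1, seed = i)$cell, numeric(1))
  tab <- table(factor(draws, levels = 1:25))
  chi <- suppressWarnings(chisq.test(tab))
  expect_gt(chi$p.value, 1e-4)
})

test_that("model evaluation reproduces the trivial AUC endpoints", {
  g <- matrix(seq(0, 24), 5, 5)
  sc <- makeScenario(list(v = g))
  ## occurrences in the three cells with v in [10, 12]
  cells <- which(g >= 10 & g <= 12, arr.ind = TRUE)
  ctr <- cbind(cells[, 2] - 0.5, 5 - cells[, 1] + 0.5)
  occ <- occurrenceSet("sp", ctr[, 1], ctr[, 2])
  tight <- envelopeModel("sp", "v", 10, 12)
  res <- evaluateModel(tight, occ, sc, nBackground = 22, seed = 5)
  expect_equal(res$auc, 1.0)            # envelope covers presences only
  expect_equal(res$n_presence, 3L)
  everything <- envelopeModel("sp", "v", -100, 100)
  resAll <- evaluateModel(everything, occ, sc, nBackground = 22, seed = 5)
  expect_equal(resAll$auc, 0.5)         # all scores tie
  resB <- evaluateModel(tight, occ, sc, nBackground = 22, seed = 5)
  expect_identical(res, resB)           # deterministic given seed
})

test_that("evaluation matches the pair-enumeration oracle on random fixtures", {
  set.seed(121)
  for (trial in 1:5) {
    sc <- randomScenario(8, 8, c("a", "b"), seed = 130 + trial)
    pts <- cbind(runif(12, 0, 8), runif(12, 0, 8))
    occ <- occurrenceSet("sp", pts[, 1], pts[, 2])
    env <- envelopeModel("sp", c("a", "b"), mins = runif(2, -6, 0),
                         maxs = runif(2, 0, 6))
    res <- evaluateModel(env, occ, sc, nBackground = 20,
                         seed = 140 + trial)
    surf <- gridValues(projectEnvelope(env, sc))
    sv <- sampleValues(sc, pts)
    cells <- unique(sv$row[sv$valid] + (sv$col[sv$valid] - 1L) * 8L)
    bg <- sampleBackground(sc, excludeCells = cells, n = 20,
                           seed = 140 + trial)
    expect_equal(res$auc, aucOracle(surf[cells], surf[bg$cell]))
  }
})

test_that("species below the unique-point cutoff do not enter the mean AUC", {
  g <- matrix(seq(0, 99), 10, 10)
  sc <- makeScenario(list(v = g))
  cellCenter <- function(r, c) c(c - 0.5, 10 - r + 0.5)
  ## species A: 12 distinct cells; species B: 3 points in one cell
  set.seed(151)
  cellsA <- cbind(sample(1:10, 12, TRUE), sample(1:10, 12, TRUE))
  cellsA <- unique(cellsA)
  while (nrow(cellsA) < 12) {
    cellsA <- unique(rbind(cellsA, c(sample(1:10, 1), sample(1:10, 1))))
  }
  ptsA <- t(apply(cellsA, 1, function(rc) cellCenter(rc[1], rc[2])))
  occ <- list(
    A = occurrenceSet("A", ptsA[, 1], ptsA[, 2]),
    B = occurrenceSet("B", rep(2.5, 3), rep(2.5, 3))
  )
  res <- suppressWarnings(
    meanAucPerVariable(occ, sc, minUnique = 10L, nBackground = 30,
                       seed = 3))
  expect_equal(res$table$n_species_used, 1L)
  detA <- res$detail[res$detail$taxon == "A", ]
  detB <- res$detail[res$detail$taxon == "B", ]
  expect_true(detA$qualifies)
  expect_equal(detB$n_env_unique, 1L)
  expect_false(detB$qualifies)
  ## the reported mean is the hand average over qualifying species
  expect_equal(res$table$mean_auc, mean(detA$auc))
})

test_that("mean AUC table averages the per-species AUCs it reports", {
  sc <- randomScenario(12, 12, c("a", "b"), seed = 161)
  set.seed(162)
  occ <- lapply(1:5, function(i) {
    pts <- cbind(runif(30, 0, 12), runif(30, 0, 12))
    occurrenceSet(paste0("sp", i), pts[, 1], pts[, 2])
  })
  names(occ) <- paste0("sp", 1:5)
  res <- meanAucPerVariable(occ, sc, minUnique = 5L, nBackground = 40,
                            seed = 8)
  for (v in c("a", "b")) {
    rows <- res$detail[res$detail$variable_set == v & res$detail$qualifies, ]
    expect_equal(res$table$mean_auc[res$table$variable == v],
                 mean(rows$auc))
  }
})

test_that("an informative variable outscores an uninformative one", {
  ## occurrences drawn from a narrow band of variable v, uniform w.r.t. w
  set.seed(171)
  nr <- 20; nc <- 20
  v <- matrix(runif(nr * nc, 0, 10), nr, nc)
  w <- matrix(runif(nr * nc, 0, 10), nr, nc)
  sc <- makeScenario(list(v = v, w = w))
  suitable <- which(v >= 4 & v <= 5)
  cells <- sample(suitable, 200, replace = TRUE)
  rr <- ((cells - 1) %% nr) + 1; cc <- ((cells - 1) %/% nr) + 1
  occ <- list(sp = occurrenceSet("sp", cc - 0.5, nr - rr + 0.5))
  res <- meanAucPerVariable(occ, sc, minUnique = 10L, seed = 4)
  aucV <- res$table$mean_auc[res$table$variable == "v"]
  aucW <- res$table$mean_auc[res$table$variable == "w"]
  expect_gt(aucV, aucW)
  expect_gt(aucV, 0.85)
})
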