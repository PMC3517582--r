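test_that("simulated trees are ultrametric, seeded and correctly sized", {
  dt <- simulateTree(nTips = 2L, birthRate = 0.5, seed = 1)
  expect_equal(nTips(dt), 2L)
  expect_gt(unname(nodeAges(dt)[3]), 0)          # single cherry, positive age
  dt16a <- simulateTree(16L, 0.3, seed = 5)
  dt16b <- simulateTree(16L, 0.3, seed = 5)
  expect_identical(ape::write.tree(apeTree(dt16a)),
                   ape::write.tree(apeTree(dt16b)))
  expect_false(identical(ape::write.tree(apeTree(dt16a)),
                         ape::write.tree(apeTree(simulateTree(16L, 0.3,
                                                              seed = 6)))))
  ages <- nodeAges(dt16a)
  expect_true(all(abs(ages[1:16]) < 1e-9))       # ultrametric tips
  pp <- posteriorProbs(dt16a)
  expect_true(all(pp >= 0.5 & pp <= 1))
})

test_that("lineage counts track the pure-birth expectation 2*exp(lambda*t)", {
  lambda <- 0.4
  tAt <- 2.5
  nReps <- 400
  counts <- vapply(seq_len(nReps), function(i) {
    dt <- simulateTree(nTips = 40L, birthRate = lambda, seed = 3000 + i)
    ages <- nodeAges(dt)
    rootAge <- ages[nTips(dt) + 1]
    ## lineages tAt after the crown = 2 + number of splits younger than
    ## rootAge - tAt but older than the stopping point
    if (rootAge < tAt) return(NA_real_)
    sum(ages[-(1:nTips(dt))] > rootAge - tAt) + 1
  }, numeric(1))
  counts <- counts[!is.na(counts)]
  expected <- 2 * exp(lambda * tAt)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.2)
})

test_that("zero rates freeze the root envelope; widths stay positive", {
  dt <- simulateTree(12L, 0.3, seed = 21)
  root <- envelopeModel("root", c("a", "b"), c(0, 5), c(2, 9))
  sim <- simulateEnvelopes(dt, root, sigma2Center = 0, sigma2LogWidth = 0,
                           seed = 3)
  for (e in sim$envelopes) {
    expect_equal(unname(e@mins), c(0, 5))
    expect_equal(unname(e@maxs), c(2, 9))
  }
  simFree <- simulateEnvelopes(dt, root, sigma2Center = 0.5,
                               sigma2LogWidth = 0.2, seed = 4)
  for (e in simFree$envelopes)
    expect_true(all(e@maxs > e@mins))   # strict: widths are exp(BM) > 0
})

test_that("tip variance of the envelope centre matches the BM rate", {
  ## var(tip centre) = rate * root age for BM from a fixed root
  root <- envelopeModel("root", "a", 0, 2)  # centre 1
  rate <- 0.3
  devs <- unlist(lapply(1:300, function(i) {
    dt <- simulateTree(4L, 0.5, seed = 4000 + i)
    sim <- simulateEnvelopes(dt, root, sigma2Center = rate,
                             sigma2LogWidth = 0, seed = 5000 + i)
    age <- unname(nodeAges(dt)[nTips(dt) + 1])
    (sim$centers[seq_len(nTips(dt)), 1] - 1) / sqrt(rate * age)
  }))
  ## standardized deviations should have unit variance
  expect_lt(abs(stats::var(devs) - 1), 0.15)
})

test_that("simulated scenarios are co-registered, in range, and seeded", {
  vars <- c("a", "b")
  scen <- simulateScenarios(vars, list(c(0, 10), c(-5, 5)),
                            gridShape = c(30L, 30L), paleoAges = c(8, 3),
                            seed = 31)
  expect_length(scen, 3L)
  expect_equal(vapply(scen, scenarioAge, numeric(1)), c(0, 8, 3))
  for (sc in scen) {
    expect_identical(variableNames(sc), vars)
    ga <- gridValues(getLayer(sc, "a"))
    expect_true(all(is.na(ga) | (ga >= 0 & ga <= 10)))
    gb <- gridValues(getLayer(sc, "b"))
    expect_true(all(is.na(gb) | (gb >= -5 & gb <= 5)))
  }
  ## the ocean mask is shared across layers and ages
  naPresent <- is.na(gridValues(getLayer(scen[[1]], "a")))
  expect_identical(is.na(gridValues(getLayer(scen[[2]], "b"))), naPresent)
  ## seeded determinism extends to bytes on disk
  d1 <- tempfile(); d2 <- tempfile()
  writeScenario(simulateScenarios(vars, list(c(0, 10), c(-5, 5)),
                                  gridShape = c(20L, 20L), paleoAges = 3,
                                  seed = 7)[[1]], d1)
  writeScenario(simulateScenarios(vars, list(c(0, 10), c(-5, 5)),
                                  gridShape = c(20L, 20L), paleoAges = 3,
                                  seed = 7)[[1]], d2)
  f1 <- file.path(d1, "a.asc"); f2 <- file.path(d2, "a.asc")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("smoothing controls spatial autocorrelation", {
  lag1 <- function(seed, scale) {
    sc <- simulateScenarios("a", list(c(0, 1)), gridShape = c(50L, 50L),
                            smoothingScale = scale, gradientWeight = 0,
                            paleoAges = numeric(0), landFraction = 1,
                            seed = seed)[[1]]
    g <- gridValues(getLayer(sc, "a"))
    stats::cor(as.vector(g[, -1]), as.vector(g[, -50]))
  }
  rough <- mean(vapply(1:5, function(s) lag1(s, 0), numeric(1)))
  smooth <- mean(vapply(1:5, function(s) lag1(s, 4), numeric(1)))
  expect_lt(abs(rough), 0.1)          # white noise: no lag-1 correlation
  expect_gt(smooth, 0.6)
})

test_that("sampled occurrences live in fully suitable cells of their envelope", {
  scen <- simulateScenarios(c("a", "b"), list(c(0, 10), c(0, 10)),
                            gridShape = c(40L, 40L), paleoAges = numeric(0),
                            seed = 41)[[1]]
  env <- envelopeModel("sp", c("a", "b"), c(3, 2), c(7, 8))
  occ <- sampleOccurrences(env, scen, n = 80, seed = 42)
  expect_equal(nOccurrences(occ), 80L)
  surf <- projectEnvelope(env, scen)
  sv <- sampleValues(scen, occ)
  expect_true(all(sv$valid))
  cells <- cbind(sv$row, sv$col)
  expect_true(all(gridValues(surf)[cells] == 1))
  ## an envelope with no suitable cell errors with a diagnostic
  bad <- envelopeModel("sp", c("a", "b"), c(100, 100), c(101, 101))
  expect_error(sampleOccurrences(bad, scen, 5, 1), "no fully suitable cell")
})

test_that("a full bundle is internally consistent and reproducible", {
  cfg <- simulationConfig(n_tips = 8L, grid_shape = c(60L, 60L),
                          n_occurrences_per_tip = 30L, seed = 51)
  b1 <- simulateBundle(cfg)
  b2 <- simulateBundle(cfg)
  expect_identical(ape::write.tree(apeTree(b1$tree)),
                   ape::write.tree(apeTree(b2$tree)))
  expect_identical(b1$trueEnvelopes$t1@mins, b2$trueEnvelopes$t1@mins)
  expect_identical(occurrenceCoords(b1$occurrences$t1),
                   occurrenceCoords(b2$occurrences$t1))
  ## every occurrence scores 1 under its own true envelope (closure)
  for (tp in c("t1", "t5")) {
    surf <- projectEnvelope(b1$trueEnvelopes[[tp]], b1$scenarios[[1]])
    sv <- sampleValues(b1$scenarios[[1]], b1$occurrences[[tp]])
    expect_true(all(gridValues(surf)[cbind(sv$row, sv$col)] == 1))
  }
  ## bundle writes a complete, reloadable study
  d <- tempfile()
  writeStudyBundle(b1, d)
  expect_true(file.exists(file.path(d, "tree.nwk")))
  expect_true(file.exists(file.path(d, "occurrences.csv")))
  expect_true(file.exists(file.path(d, "true_envelopes.csv")))
  back <- readScenario(file.path(d, "scenario_present", "manifest.yml"))
  expect_identical(gridValues(getLayer(back, cfg$variables[1])),
                   gridValues(getLayer(b1$scenarios[[1]],
                                       cfg$variables[1])))
})
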