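## Synthetic study generator: pure-birth trees, Brownian envelope evolution,
## spatially autocorrelated climate scenarios and occurrence records with
## known ground truth.  Every pipeline stage can be exercised - and its
## calibration checked - against data whose generating parameters are known.
##
## All randomness flows from a single integer seed: each sub-stage draws
## from a sub-seed derived deterministically from (seed, stage index), so
## regenerating any one stage reproduces it exactly.

#' Simulate a pure-birth (Yule) dated tree
#'
#' Forward simulation: starting from two lineages at the crown, each lineage
#' splits at rate \code{birthRate}; the process stops when \code{nTips}
#' lineages exist, plus one further exponential waiting time so the last
#' split is not at the present.  The result is ultrametric with branch
#' lengths in Ma.  Internal nodes receive synthetic posterior probabilities
#' (root 1, others uniform on \[0.5, 1\], rounded to 2 digits) so that
#' support filtering can be exercised downstream.
#'
#' @param nTips number of tips (>= 2).
#' @param birthRate speciation rate per lineage per Ma.
#' @param seed integer seed.
#' @return a [DatedTree-class] with tips labelled \code{t1..tn}.
#' @export
simulateTree <- function(nTips = 38L, birthRate = 0.17, seed = 1L) {
  stopifnot(nTips >= 2L, birthRate > 0)
  withSeed(seed, {
    maxNodes <- 2L * nTips
    tstart <- numeric(maxNodes)
    kids <- vector("list", maxNodes)
    active <- c(1L, 2L)          # crown starts as two lineages at t = 0
    tstart[1:2] <- 0
    nxt <- 3L
    t <- 0
    while (length(active) < nTips) {
      t <- t + stats::rexp(1L, rate = length(active) * birthRate)
      i <- if (length(active) == 1L) active else sample(active, 1L)
      kids[[i]] <- c(nxt, nxt + 1L)
      tstart[nxt] <- tstart[nxt + 1L] <- t
      active <- c(setdiff(active, i), nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    t <- t + stats::rexp(1L, rate = length(active) * birthRate)
    tipCounter <- 0L
    buildNewick <- function(i) {
      if (is.null(kids[[i]])) {
        tipCounter <<- tipCounter + 1L
        sprintf("t%d:%s", tipCounter, formatExact(t - tstart[i]))
      } else {
        tEnd <- tstart[kids[[i]][1L]]
        sprintf("(%s,%s):%s", buildNewick(kids[[i]][1L]),
                buildNewick(kids[[i]][2L]), formatExact(tEnd - tstart[i]))
      }
    }
    nwk <- sprintf("(%s,%s);", buildNewick(1L), buildNewick(2L))
    phy <- ape::read.tree(text = nwk)
    pp <- round(stats::runif(phy$Nnode, 0.5, 1), 2)
    pp[1L] <- 1                      # root
    phy$node.label <- formatExact(pp)
    datedTree(phy)
  })
}

#' Simulate Brownian motion of one character on a tree
#'
#' @param x a [DatedTree-class].
#' @param rootState state at the root.
#' @param sigma2 Brownian rate (units^2 per Ma).
#' @param seed integer seed.
#' @return numeric vector of states for all nodes, indexed by node id
#'   (tips 1..n, internals n+1..).
#' @export
simulateBM <- function(x, rootState = 0, sigma2 = 1, seed = 1L) {
  stopifnot(is(x, "DatedTree"), sigma2 >= 0)
  tr <- x@tree
  n <- length(tr$tip.label)
  withSeed(seed, {
    state <- numeric(n + tr$Nnode)
    state[n + 1L] <- rootState
    ## edges in preorder so parents are set before children
    ord <- ape::reorder.phylo(tr, "cladewise")
    steps <- stats::rnorm(nrow(ord$edge), 0,
                          sqrt(sigma2 * ord$edge.length))
    for (e in seq_len(nrow(ord$edge)))
      state[ord$edge[e, 2L]] <- state[ord$edge[e, 1L]] + steps[e]
    state
  })
}

#' Simulate envelope evolution along a tree
#'
#' Per climate variable, the envelope \emph{centre} and the \emph{log
#' width} evolve as independent Brownian motions along the tree; each
#' node's bounds are then centre -/+ width/2, so every simulated envelope
#' is valid (\code{max >= min}) by construction.  The inference stage still
#' reconstructs min and max independently, so the generator deliberately
#' probes that modelling simplification.
#'
#' @param x a [DatedTree-class].
#' @param rootEnvelope the [EnvelopeModel-class] at the root.
#' @param sigma2Center per-variable Brownian rate of the centre
#'   (units^2/Ma; recycled).
#' @param sigma2LogWidth per-variable Brownian rate of log width
#'   (recycled).
#' @param seed integer seed.
#' @return list with \code{envelopes} (named list of
#'   [EnvelopeModel-class]: tips by tip label, internal nodes by node id)
#'   and matrices \code{centers}, \code{widths} (nodes x variables).
#' @export
simulateEnvelopes <- function(x, rootEnvelope, sigma2Center = 0.1,
                              sigma2LogWidth = 0.02, seed = 1L) {
  stopifnot(is(x, "DatedTree"), is(rootEnvelope, "EnvelopeModel"))
  tr <- x@tree
  n <- length(tr$tip.label)
  vars <- rootEnvelope@variables
  sigma2Center <- rep_len(sigma2Center, length(vars))
  sigma2LogWidth <- rep_len(sigma2LogWidth, length(vars))
  N <- n + tr$Nnode
  centers <- widths <- matrix(NA_real_, N, length(vars),
                              dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    c0 <- (rootEnvelope@mins[j] + rootEnvelope@maxs[j]) / 2
    w0 <- rootEnvelope@maxs[j] - rootEnvelope@mins[j]
    if (w0 <= 0)
      stop("root envelope must have positive width for '", vars[j], "'")
    centers[, j] <- simulateBM(x, c0, sigma2Center[j],
                               seed = subSeed(seed, 2L * j))
    widths[, j] <- exp(simulateBM(x, log(w0), sigma2LogWidth[j],
                                  seed = subSeed(seed, 2L * j + 1L)))
  }
  ids <- c(tr$tip.label, as.character(seq_len(tr$Nnode) + n))
  envs <- lapply(seq_len(N), function(i)
    envelopeModel(ids[i], vars, centers[i, ] - widths[i, ] / 2,
                  centers[i, ] + widths[i, ] / 2))
  names(envs) <- ids
  list(envelopes = envs, centers = centers, widths = widths)
}

## separable Gaussian smoothing with edge renormalization
smoothField <- function(nr, nc, scale) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (scale <= 0) return(z)
  half <- max(1L, ceiling(3 * scale))
  k <- stats::dnorm(seq(-half, half), sd = scale)
  sm1 <- function(v) {
    m <- length(v)
    out <- stats::filter(c(rep(0, half), v, rep(0, half)), k,
                         sides = 2)[(half + 1):(half + m)]
    norm <- stats::filter(c(rep(0, half), rep(1, m), rep(0, half)), k,
                          sides = 2)[(half + 1):(half + m)]
    as.numeric(out / norm)
  }
  z <- apply(z, 2L, sm1)
  z <- t(apply(z, 1L, sm1))
  (z - mean(z)) / stats::sd(z)
}

#' Simulate present-day and paleo climate scenarios
#'
#' Each variable's present-day layer is a smoothed (spatially
#' autocorrelated) Gaussian field blended with a north-south gradient and
#' min-max rescaled to the variable's configured range.  Paleo layers add a
#' second smooth anomaly field whose amplitude grows linearly with age, then
#' rescale to the same range, so older scenarios drift smoothly away from
#' the present.  An optional smooth "ocean" mask (shared by all layers and
#' ages, like a coastline) introduces no-data cells.
#'
#' @param variables climate variable names.
#' @param ranges list or 2-row matrix of per-variable (min, max) value
#'   ranges, in variable order.
#' @param gridShape c(rows, cols).
#' @param xll,yll,cellsize georeferencing of the common grid.
#' @param smoothingScale autocorrelation length in cells (0 = white noise).
#' @param gradientWeight weight of the latitudinal gradient relative to the
#'   noise field (0..1).
#' @param paleoAges ages (Ma) of the paleo scenarios to derive.
#' @param paleoShift anomaly amplitude, in within-range standard
#'   deviations per 10 Ma of age.
#' @param landFraction fraction of cells kept as land (1 = no ocean mask).
#' @param seed integer seed.
#' @return list of [ClimateScenario-class]: present first (age 0), then one
#'   per paleo age.
#' @export
simulateScenarios <- function(variables, ranges, gridShape = c(100L, 100L),
                              xll = -125, yll = 32, cellsize = 0.1,
                              smoothingScale = 5, gradientWeight = 0.4,
                              paleoAges = c(10, 8, 3), paleoShift = 0.5,
                              landFraction = 0.92, seed = 1L) {
  if (is.matrix(ranges)) ranges <- asplit(ranges, 2L)
  stopifnot(length(ranges) == length(variables))
  nr <- gridShape[1L]; nc <- gridShape[2L]
  withSeed(seed, {
    latGrad <- matrix(rev(seq_len(nr)), nr, nc)    # south low, north high
    latGrad <- (latGrad - mean(latGrad)) / stats::sd(latGrad)
    ocean <- if (landFraction < 1) {
      f <- smoothField(nr, nc, smoothingScale * 2)
      f < stats::quantile(f, 1 - landFraction)
    } else matrix(FALSE, nr, nc)
    base <- lapply(variables, function(v)
      (1 - gradientWeight) * smoothField(nr, nc, smoothingScale) +
        gradientWeight * latGrad)
    shift <- lapply(variables, function(v)
      smoothField(nr, nc, smoothingScale))
    mkScenario <- function(name, age) {
      layers <- lapply(seq_along(variables), function(j) {
        f <- base[[j]] + (age / 10) * paleoShift * shift[[j]]
        rng <- range(f)
        lo <- ranges[[j]][1L]; hi <- ranges[[j]][2L]
        g <- lo + (f - rng[1L]) / (rng[2L] - rng[1L]) * (hi - lo)
        g[ocean] <- NA_real_
        climateLayer(variables[j], g, xll, yll, cellsize)
      })
      climateScenario(name, age, layers)
    }
    c(list(mkScenario("present", 0)),
      lapply(paleoAges, function(a) mkScenario(sprintf("%gMa", a), a)))
  })
}

#' Sample occurrence points from a tip's envelope
#'
#' Projects the (true) envelope into the scenario and draws \code{n} points
#' uniformly from the cells scored fully suitable (value 1), placing each
#' point uniformly at random inside its cell, so re-sampling the scenario
#' at the point recovers the cell exactly.
#'
#' @param envelope the tip's [EnvelopeModel-class].
#' @param scenario a [ClimateScenario-class].
#' @param n number of points.
#' @param seed integer seed.
#' @return an [OccurrenceSet-class] with source \code{"synthetic"}.
#' @export
sampleOccurrences <- function(envelope, scenario, n = 100L, seed = 1L) {
  surf <- projectEnvelope(envelope, scenario)
  suitable <- which(!is.na(surf@grid) & surf@grid == 1)
  if (!length(suitable))
    stop(sprintf(paste0("no fully suitable cell for '%s' in scenario '%s';",
                        " envelope outside the simulated climate range"),
                 envelope@taxon, scenario@name))
  d <- dim(surf@grid)
  withSeed(seed, {
    cells <- suitable[sample.int(length(suitable), n, replace = TRUE)]
    row <- ((cells - 1L) %% d[1L]) + 1L
    col <- ((cells - 1L) %/% d[1L]) + 1L
    ctr <- cellCenters(row, col, surf@xll, surf@yll, surf@cellsize, d[1L])
    lon <- ctr[, 1L] + stats::runif(n, -0.499, 0.499) * surf@cellsize
    lat <- ctr[, 2L] + stats::runif(n, -0.499, 0.499) * surf@cellsize
    occurrenceSet(envelope@taxon, lon, lat, source = "synthetic")
  })
}

#' Default simulation configuration
#'
#' The default study emulates a clade of western North American
#' drought-adapted herbs: 38 tips, crown age of order 15-20 Ma (birth rate
#' 0.17/Ma), four climate variables with root bounds and Brownian rates
#' chosen so that tip envelope dispersion matches the order of magnitude
#' seen in published envelope tables for such clades, 100x100 degree-scale
#' grids over the Great Basin / Sierra Nevada window, and paleo scenarios
#' at 10, 8 and 3 Ma.
#'
#' @param ... overrides for any element of the returned list.
#' @return named list of simulation parameters; see [simulateBundle()].
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    n_tips = 38L,
    birth_rate = 0.17,
    variables = c("Standard_deviation_of_mean_temperature",
                  "Mean_daily_precipitation_in_warmest_month",
                  "Mean_daily_precipitation_in_coolest_month",
                  "Mean_temperature_in_coolest_month"),
    root_min = c(7.1, 0.1, 0.1, -5.0),
    root_max = c(10.3, 1.3, 5.5, 3.6),
    ## NULL = derive each variable's climate range from the simulated
    ## envelopes (span of all node bounds plus half a root width per side),
    ## mirroring how a real study region's grids necessarily span the
    ## climates at every species' localities
    ranges = NULL,
    ## niche-conservatism regime: drift over the expected crown age (~16 Ma
    ## at these tip/birth settings) has standard deviation of about a
    ## quarter of the root envelope width for the centre, and about 0.25 on
    ## the log-width scale (widths vary by ~25%); sigma2 = (sd)^2 / 16
    sigma2_center = c(0.04, 0.006, 0.11, 0.28),
    sigma2_logwidth = 0.004,
    grid_shape = c(100L, 100L),
    xll = -125, yll = 32, cellsize = 0.1,
    smoothing_scale = 5,
    gradient_weight = 0.4,
    paleo_ages = c(10, 8, 3),
    paleo_shift = 0.5,
    land_fraction = 0.92,
    n_occurrences_per_tip = 100L,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

#' Simulate a complete study bundle with ground truth
#'
#' Chains [simulateTree()], [simulateEnvelopes()], [simulateScenarios()]
#' and [sampleOccurrences()] under one seed, returning every intermediate
#' truth needed to score the pipeline's estimates.
#'
#' @param config a [simulationConfig()] list.
#' @param seed overrides \code{config$seed} when given.
#' @return list: \code{tree} ([DatedTree-class]), \code{trueEnvelopes}
#'   (named list over all nodes), \code{scenarios} (present first),
#'   \code{occurrences} (named list per tip), \code{config}.
#' @export
simulateBundle <- function(config = simulationConfig(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  s <- config$seed
  tree <- simulateTree(config$n_tips, config$birth_rate,
                       seed = subSeed(s, 1L))
  root <- envelopeModel("root", config$variables, config$root_min,
                        config$root_max)
  sim <- simulateEnvelopes(tree, root, config$sigma2_center,
                           config$sigma2_logwidth, seed = subSeed(s, 2L))
  ranges <- config$ranges
  if (is.null(ranges)) {
    margin <- (root@maxs - root@mins) / 2
    ranges <- lapply(seq_along(config$variables), function(j) {
      lows <- vapply(sim$envelopes, function(e) e@mins[j], numeric(1))
      highs <- vapply(sim$envelopes, function(e) e@maxs[j], numeric(1))
      c(min(lows) - margin[j], max(highs) + margin[j])
    })
  }
  ## The study region must offer every tip at least one fully suitable
  ## cell (as a real study region, chosen around the species, would).  A
  ## random field draw occasionally leaves one tip's joint climate
  ## condition unmet anywhere; such draws are rejected and the scenario
  ## fields redrawn under a deterministic sub-seed, leaving the tree and
  ## envelope truth untouched.  Persistent failure is an error.
  tips <- apeTree(tree)$tip.label
  scenarios <- NULL
  for (attempt in seq_len(20L)) {
    cand <- simulateScenarios(
      config$variables, ranges, gridShape = config$grid_shape,
      xll = config$xll, yll = config$yll, cellsize = config$cellsize,
      smoothingScale = config$smoothing_scale,
      gradientWeight = config$gradient_weight,
      paleoAges = config$paleo_ages, paleoShift = config$paleo_shift,
      landFraction = config$land_fraction,
      seed = subSeed(s, 3L + 1000L * (attempt - 1L)))
    covered <- all(vapply(tips, function(tp) {
      surf <- projectEnvelope(sim$envelopes[[tp]], cand[[1L]])
      any(surf@grid == 1, na.rm = TRUE)
    }, logical(1)))
    if (covered) { scenarios <- cand; break }
  }
  if (is.null(scenarios))
    stop("could not draw a scenario covering every tip envelope; ",
         "widen 'ranges' or enlarge 'grid_shape'")
  occ <- lapply(seq_along(tips), function(i)
    sampleOccurrences(sim$envelopes[[tips[i]]], scenarios[[1L]],
                      n = config$n_occurrences_per_tip,
                      seed = subSeed(s, 100L + i)))
  names(occ) <- tips
  list(tree = tree, trueEnvelopes = sim$envelopes, scenarios = scenarios,
       occurrences = occ, config = config)
}

#' Write a study bundle to disk
#'
#' Lays out a complete input set for the pipeline: one directory with
#' rasters + manifest per scenario, an occurrence CSV, the dated tree in
#' Newick, and the true envelope bounds as CSV truth tables.
#'
#' @param bundle output of [simulateBundle()].
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
writeStudyBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sc in bundle$scenarios)
    writeScenario(sc, file.path(dir, paste0("scenario_", sc@name)))
  writeOccurrences(bundle$occurrences, file.path(dir, "occurrences.csv"))
  writeDatedTree(bundle$tree, file.path(dir, "tree.nwk"))
  writeEnvelopes(bundle$trueEnvelopes, file.path(dir, "true_envelopes.csv"))
  invisible(dir)
}
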