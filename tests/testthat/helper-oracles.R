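## Shared fixture builders and independent oracles.  The oracles are kept
## deliberately naive (dense algebra, double loops, exhaustive enumeration)
## so they share no code path with the implementation they check.

makeLayer <- function(mat, var = "v1", xll = 0, yll = 0, cs = 1)
  climateLayer(var, mat, xll, yll, cs)

makeScenario <- function(mats, age = 0, name = "test",
                         xll = 0, yll = 0, cs = 1) {
  layers <- lapply(names(mats), function(v)
    climateLayer(v, mats[[v]], xll, yll, cs))
  climateScenario(name, age, layers)
}

randomScenario <- function(nr, nc, vars, seed, xll = 0, yll = 0, cs = 1,
                           naFrac = 0) {
  set.seed(seed)
  mats <- lapply(vars, function(v) {
    m <- matrix(stats::runif(nr * nc, -10, 10), nr, nc)
    if (naFrac > 0)
      m[sample.int(nr * nc, round(naFrac * nr * nc))] <- NA_real_
    m
  })
  makeScenario(stats::setNames(mats, vars), xll = xll, yll = yll, cs = cs)
}

toyTree <- function(text) datedTree(ape::read.tree(text = text))

## dense GLS reconstruction oracle: explicit phylogenetic covariance,
## GLS root mean, conditional expectation for every internal node
glsReconstructOracle <- function(phy, x) {
  C <- ape::vcv(phy)
  xv <- x[rownames(C)]
  n <- length(xv)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric((t(one) %*% Ci %*% xv) / (t(one) %*% Ci %*% one))
  dep <- ape::node.depth.edgelength(phy)
  M <- ape::mrca(phy, full = TRUE)
  internals <- seq_len(phy$Nnode) + n
  states <- vapply(internals, function(nd) {
    covNodeTips <- dep[M[nd, seq_len(n)]]
    mu + as.numeric(covNodeTips %*% Ci %*% (xv - mu))
  }, numeric(1))
  ss <- as.numeric(t(xv - mu) %*% Ci %*% (xv - mu))
  list(states = stats::setNames(states, internals),
       sigma2_ml = ss / n, rootState = states[1L])
}

## per-cell counting oracle for envelope projection
projectionOracle <- function(model, scenario) {
  d <- gridDim(scenario)
  L <- length(variableNames(model))
  out <- matrix(NA_real_, d[1L], d[2L])
  b <- envelopeBounds(model)
  for (r in seq_len(d[1L])) {
    for (c in seq_len(d[2L])) {
      vals <- vapply(b$variable, function(v)
        gridValues(getLayer(scenario, v))[r, c], numeric(1))
      if (anyNA(vals)) next
      out[r, c] <- sum(vals >= b$min & vals <= b$max) / L
    }
  }
  out
}

## exhaustive pairwise AUC oracle with half-credit ties
aucOracle <- function(p, b) {
  tot <- 0
  for (x in p) for (y in b)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(p) * length(b))
}

intervalJaccard <- function(min1, max1, min2, max2) {
  inter <- max(0, min(max1, max2) - max(min1, min2))
  union <- max(max1, max2) - min(min1, min2)
  if (union == 0) return(as.numeric(min1 == min2))  # both degenerate
  inter / union
}

## random ultrametric tree via the package-independent ape coalescent
randomUltrametricTree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rcoal(n)
  phy$edge.length <- phy$edge.length * stats::runif(1, 0.5, 2)
  phy
}
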