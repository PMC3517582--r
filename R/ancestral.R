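## Maximum-likelihood ancestral reconstruction of continuous characters
## under Brownian motion, applied independently to the lower and upper
## envelope bound of each climate variable.
##
## The joint-ML node states under BM maximize the product of the Gaussian
## edge transitions, i.e. minimize sum over edges of (difference)^2 / length.
## Setting the gradient to zero makes every internal state the
## inverse-branch-length-weighted mean of its neighbours' states, a sparse
## linear system solved here directly.  Profiling out the internal states
## leaves the tip quadratic form (x - mu)' C^{-1} (x - mu) with C the
## phylogenetic covariance, so the minimized edge sum also yields the ML
## rate and log-likelihood without a second pass.

#' ML Brownian-motion reconstruction of one character
#'
#' Estimates the joint maximum-likelihood states of a continuous character
#' at every internal node of a dated tree under Brownian motion, together
#' with the ML rate \eqn{\sigma^2} (divisor n, the number of tips; the
#' REML-style rate with divisor n-1 is reported alongside) and the
#' log-likelihood at the optimum.  States obey the maximum principle: each
#' lies within the range of the tip values, because every internal state is
#' a branch-length-weighted average of its neighbours.
#'
#' Zero-length edges are collapsed by merging their endpoints, which then
#' share a state (with a warning); two tips with different values joined by
#' a zero-length path are an error.
#'
#' @param x a [DatedTree-class].
#' @param tipValues numeric vector of tip states, named by tip label (or
#'   unnamed in tip order); all finite.
#' @return list with \code{states} (named numeric, ML states indexed by
#'   internal node id), \code{sigma2_ml}, \code{sigma2_reml},
#'   \code{loglik}, \code{rootState} and \code{n} (tip count).
#' @seealso [reconstructEnvelopes()]
#' @export
reconstructBM <- function(x, tipValues) {
  stopifnot(is(x, "DatedTree"))
  tr <- x@tree
  n <- length(tr$tip.label)
  if (n < 2L) stop("reconstruction needs at least 2 tips")
  if (is.null(names(tipValues))) {
    if (length(tipValues) != n)
      stop("unnamed 'tipValues' must have one value per tip")
    names(tipValues) <- tr$tip.label
  }
  miss <- setdiff(tr$tip.label, names(tipValues))
  if (length(miss))
    stop("tip values missing for: ", paste(miss, collapse = ", "))
  vals <- as.numeric(tipValues[tr$tip.label])
  if (any(!is.finite(vals))) stop("tip values must be finite")

  N <- n + tr$Nnode
  parent <- tr$edge[, 1L]; child <- tr$edge[, 2L]
  len <- tr$edge.length

  ## collapse zero-length edges: child joins its parent's group
  rep_ <- seq_len(N)
  find <- function(i) { while (rep_[i] != i) i <- rep_[i]; i }
  zero <- len == 0
  if (any(zero)) {
    warning(sprintf("%d zero-length edge(s) collapsed; merged nodes share a state",
                    sum(zero)))
    for (e in which(zero)) rep_[find(child[e])] <- find(parent[e])
  }
  grp <- vapply(seq_len(N), find, integer(1))

  ## groups pinned by tips
  pinned <- rep(NA_real_, N)
  for (i in seq_len(n)) {
    g <- grp[i]
    if (!is.na(pinned[g]) && pinned[g] != vals[i])
      stop("tips with different values are joined by a zero-length path")
    pinned[g] <- vals[i]
  }

  unknown <- setdiff(unique(grp), unique(grp[seq_len(n)]))
  k <- length(unknown)
  pos <- integer(N); pos[unknown] <- seq_len(k)
  A <- matrix(0, k, k)
  b <- numeric(k)
  for (e in which(!zero)) {
    gp <- grp[parent[e]]; gc <- grp[child[e]]
    if (gp == gc) next
    w <- 1 / len[e]
    for (side in 1:2) {
      g1 <- if (side == 1L) gp else gc
      g2 <- if (side == 1L) gc else gp
      if (is.na(pinned[g1])) {
        i <- pos[g1]
        A[i, i] <- A[i, i] + w
        if (is.na(pinned[g2])) {
          A[i, pos[g2]] <- A[i, pos[g2]] - w
        } else {
          b[i] <- b[i] + w * pinned[g2]
        }
      }
    }
  }
  sol <- if (k) solve(A, b) else numeric(0)
  stateOf <- pinned
  stateOf[unknown] <- sol
  nodeState <- stateOf[grp]

  ## minimized edge sum = (x - mu)' C^{-1} (x - mu)
  ss <- sum((nodeState[parent[!zero]] - nodeState[child[!zero]])^2 /
              len[!zero])
  sigma2_ml <- ss / n
  sigma2_reml <- ss / (n - 1)
  C <- ape::vcv(tr)
  ldet <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  loglik <- if (sigma2_ml > 0)
    -0.5 * (n * log(2 * pi * sigma2_ml) + ldet + n)
  else Inf   # degenerate: all tips equal, point mass

  internals <- seq_len(tr$Nnode) + n
  list(states = stats::setNames(nodeState[internals], internals),
       sigma2_ml = sigma2_ml, sigma2_reml = sigma2_reml,
       loglik = loglik, rootState = nodeState[n + 1L], n = n)
}

#' Reconstruct ancestral envelopes at every node
#'
#' Runs [reconstructBM()] independently for each (variable, bound)
#' character - the lower and the upper bound of every climate variable, 2L
#' characters for L variables - and assembles the per-node states into
#' ancestral [EnvelopeModel-class] objects.  Because bounds are
#' reconstructed independently, a node can in principle receive
#' \code{max < min}; such intervals are repaired by collapsing both bounds
#' to their midpoint, and every repair is logged in the output.
#'
#' @param x a [DatedTree-class].
#' @param tipEnvelopes named list of [EnvelopeModel-class], one per tip
#'   label, all sharing the same variable set.
#' @return list with:
#'   \item{envelopes}{named list of [EnvelopeModel-class], one per internal
#'     node id.}
#'   \item{rates}{data frame, one row per character: \code{variable},
#'     \code{bound}, \code{sigma2_ml}, \code{sigma2_reml}, \code{loglik}.}
#'   \item{repairs}{data frame of midpoint repairs (\code{node},
#'     \code{variable}, \code{min_raw}, \code{max_raw}, \code{midpoint}).}
#' @export
reconstructEnvelopes <- function(x, tipEnvelopes) {
  stopifnot(is(x, "DatedTree"))
  tr <- x@tree
  tips <- tr$tip.label
  miss <- setdiff(tips, names(tipEnvelopes))
  if (length(miss))
    stop("tip envelopes missing for: ", paste(miss, collapse = ", "))
  vars <- variableNames(tipEnvelopes[[tips[1L]]])
  for (tp in tips) {
    if (!identical(sort(variableNames(tipEnvelopes[[tp]])), sort(vars)))
      stop("tip '", tp, "' has a different variable set")
  }
  n <- length(tips)
  internals <- seq_len(tr$Nnode) + n
  lower <- upper <- matrix(NA_real_, length(internals), length(vars),
                           dimnames = list(internals, vars))
  rates <- list()
  for (v in vars) {
    for (bound in c("min", "max")) {
      tv <- vapply(tipEnvelopes[tips], function(e) {
        i <- match(v, e@variables)
        if (bound == "min") e@mins[i] else e@maxs[i]
      }, numeric(1))
      names(tv) <- tips
      rec <- reconstructBM(x, tv)
      if (bound == "min") lower[, v] <- rec$states
      else upper[, v] <- rec$states
      rates[[paste(v, bound)]] <- data.frame(
        variable = v, bound = bound, sigma2_ml = rec$sigma2_ml,
        sigma2_reml = rec$sigma2_reml, loglik = rec$loglik)
    }
  }
  repairs <- list()
  envs <- list()
  for (i in seq_along(internals)) {
    mins <- lower[i, ]; maxs <- upper[i, ]
    bad <- which(maxs < mins)
    for (j in bad) {
      mid <- (mins[j] + maxs[j]) / 2
      repairs[[length(repairs) + 1L]] <- data.frame(
        node = internals[i], variable = vars[j],
        min_raw = mins[j], max_raw = maxs[j], midpoint = mid)
      mins[j] <- maxs[j] <- mid
    }
    envs[[as.character(internals[i])]] <-
      envelopeModel(as.character(internals[i]), vars, mins, maxs)
  }
  list(envelopes = envs,
       rates = do.call(rbind, rates),
       repairs = if (length(repairs)) do.call(rbind, repairs) else
         data.frame(node = integer(), variable = character(),
                    min_raw = numeric(), max_raw = numeric(),
                    midpoint = numeric()))
}

#' Write ancestral (or tip) envelopes as a wide bounds table
#'
#' One row per taxon/node, a Max and a Min column per variable: the layout
#' in which envelope bounds tables are conventionally published.
#'
#' @param envList list of [EnvelopeModel-class].
#' @param path CSV path.
#' @return \code{path}, invisibly.
#' @export
writeBoundsTable <- function(envList, path) {
  if (is(envList, "EnvelopeModel")) envList <- list(envList)
  vars <- variableNames(envList[[1L]])
  rows <- lapply(envList, function(e) {
    out <- data.frame(taxon = e@taxon, n_points = e@nPoints)
    for (v in vars) {
      i <- match(v, e@variables)
      out[[paste0(v, "_max")]] <- e@maxs[i]
      out[[paste0(v, "_min")]] <- e@mins[i]
    }
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
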