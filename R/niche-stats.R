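## Niche-overlap statistics on suitability surfaces (Schoener's D and the
## Hellinger-based I) and the age-range correlation test of overlap against
## divergence time.

#' Normalize a suitability surface to a probability surface
#'
#' Divides the non-missing cells by their sum so the surface integrates to
#' one, the form required by the overlap statistics.
#'
#' @param surface a [SuitabilitySurface-class] or numeric matrix with
#'   \code{NA} for masked cells; must have a positive total.
#' @return numeric matrix summing to 1 over non-\code{NA} cells.
#' @export
normalizeSurface <- function(surface) {
  g <- if (is(surface, "SuitabilitySurface")) surface@grid else surface
  tot <- sum(g, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0)
    stop("surface has no positive cells; cannot normalize")
  g / tot
}

#' Niche overlap between two probability surfaces
#'
#' Schoener's \eqn{D = 1 - \frac12 \sum_i |p_{X,i} - p_{Y,i}|} and the
#' Hellinger-based \eqn{I = 1 - \frac12 \sum_i (\sqrt{p_{X,i}} -
#' \sqrt{p_{Y,i}})^2}, both in \[0, 1\]: 1 for identical surfaces, 0 for
#' disjoint ones.  The two surfaces are restricted to their common
#' non-missing mask and renormalized on it before comparison, so differing
#' no-data footprints do not masquerade as niche differences.
#'
#' @param pX,pY [SuitabilitySurface-class] objects or matrices on a common
#'   grid (same dimensions).
#' @return a single numeric overlap value.
#' @export
overlapD <- function(pX, pY) overlapStat(pX, pY, "D")

#' @rdname overlapD
#' @export
overlapI <- function(pX, pY) overlapStat(pX, pY, "I")

overlapStat <- function(pX, pY, statistic = c("D", "I")) {
  statistic <- match.arg(statistic)
  gx <- if (is(pX, "SuitabilitySurface")) pX@grid else pX
  gy <- if (is(pY, "SuitabilitySurface")) pY@grid else pY
  if (!identical(dim(gx), dim(gy)))
    stop("surfaces are on different grids")
  mask <- !is.na(gx) & !is.na(gy)
  if (!any(mask)) stop("no common non-missing cells")
  x <- normalizeSurface(ifelse(mask, gx, NA_real_))[mask]
  y <- normalizeSurface(ifelse(mask, gy, NA_real_))[mask]
  if (statistic == "D") 1 - 0.5 * sum(abs(x - y))
  else 1 - 0.5 * sum((sqrt(x) - sqrt(y))^2)
}

#' Pairwise niche-overlap matrices
#'
#' Computes D and I for every unordered pair of taxa, mirrored into
#' symmetric matrices with unit diagonal.
#'
#' @param surfaces named list of [SuitabilitySurface-class] objects (or
#'   matrices) on a common grid, one per taxon; at least two.
#' @return list with symmetric matrices \code{D} and \code{I}.
#' @seealso [overlapSummary()], [ageRangeCorrelation()]
#' @export
overlapMatrix <- function(surfaces) {
  taxa <- names(surfaces)
  if (length(surfaces) < 2L || is.null(taxa))
    stop("need a named list of at least two surfaces")
  k <- length(taxa)
  D <- I <- matrix(1, k, k, dimnames = list(taxa, taxa))
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      D[i, j] <- D[j, i] <- overlapD(surfaces[[i]], surfaces[[j]])
      I[i, j] <- I[j, i] <- overlapI(surfaces[[i]], surfaces[[j]])
    }
  }
  list(D = D, I = I)
}

#' Mean overlap over pair sets
#'
#' Arithmetic means of the pairwise overlaps over (a) all unordered pairs,
#' (b) pairs within a named clade (all tip descendants of a given node) and
#' (c) sister species pairs (cherries of the tree).
#'
#' @param overlap output of [overlapMatrix()].
#' @param tree optional [DatedTree-class] for the clade and sister-pair
#'   summaries.
#' @param clades optional named list of node ids; each adds a within-clade
#'   mean.
#' @return data frame with columns \code{set}, \code{statistic},
#'   \code{mean}, \code{n_pairs}.
#' @export
overlapSummary <- function(overlap, tree = NULL, clades = NULL) {
  meanPairs <- function(m, taxa) {
    taxa <- intersect(taxa, rownames(m))
    if (length(taxa) < 2L) return(c(NA_real_, 0))
    v <- m[taxa, taxa][upper.tri(matrix(0, length(taxa), length(taxa)))]
    c(mean(v), length(v))
  }
  sets <- list(all = rownames(overlap$D))
  if (!is.null(tree) && !is.null(clades)) {
    tr <- apeTree(tree)
    for (nm in names(clades)) {
      desc <- cladeTips(tr, clades[[nm]])
      sets[[nm]] <- desc
    }
  }
  rows <- list()
  for (nm in names(sets)) {
    for (st in c("D", "I")) {
      mp <- meanPairs(overlap[[st]], sets[[nm]])
      rows[[paste(nm, st)]] <- data.frame(
        set = nm, statistic = st, mean = mp[1L], n_pairs = mp[2L])
    }
  }
  if (!is.null(tree)) {
    ch <- sisterPairs(tree)
    for (st in c("D", "I")) {
      v <- apply(ch, 1L, function(p)
        if (all(p %in% rownames(overlap[[st]])))
          overlap[[st]][p[1L], p[2L]] else NA_real_)
      v <- v[!is.na(v)]
      rows[[paste("sister", st)]] <- data.frame(
        set = "sister_pairs", statistic = st,
        mean = if (length(v)) mean(v) else NA_real_, n_pairs = length(v))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

cladeTips <- function(tr, node) {
  n <- length(tr$tip.label)
  if (node <= n) return(tr$tip.label[node])
  tr$tip.label[intersect(seq_len(n),
                         tipDescendants(tr, node))]
}

## tip descendants of a node by simple stack walk
tipDescendants <- function(tr, node) {
  out <- integer(0)
  stack <- node
  n <- length(tr$tip.label)
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= n) out <- c(out, v)
    else stack <- c(stack, tr$edge[tr$edge[, 1L] == v, 2L])
  }
  out
}

#' Sister species pairs (cherries)
#'
#' @param x a [DatedTree-class].
#' @return two-column character matrix of tip-label pairs whose MRCA has
#'   exactly those two tips as descendants.
#' @export
sisterPairs <- function(x) {
  stopifnot(is(x, "DatedTree"))
  tr <- x@tree
  n <- length(tr$tip.label)
  out <- NULL
  for (v in seq_len(tr$Nnode) + n) {
    kids <- tr$edge[tr$edge[, 1L] == v, 2L]
    if (length(kids) == 2L && all(kids <= n))
      out <- rbind(out, tr$tip.label[kids])
  }
  if (is.null(out)) out <- matrix(character(), 0, 2)
  colnames(out) <- c("tip1", "tip2")
  out
}

#' Age-range correlation with a permutation null
#'
#' Regresses the pairwise niche overlap of two taxa on the age of their
#' most recent common ancestor by ordinary least squares.  A negative slope
#' indicates niche divergence with time.  Because the n(n-1)/2 pairs are
#' not independent (pairs share taxa), significance is assessed by a
#' permutation null that jointly relabels the rows and columns of the
#' overlap matrix and recomputes the slope; the reported p-value is the
#' smoothed proportion \eqn{(1 + \#\{|slope_{perm}| \ge |slope_{obs}|\}) /
#' (1 + n_{perm})}.  The parametric regression p-value is reported
#' alongside for reference.
#'
#' @param overlap output of [overlapMatrix()] (or one symmetric overlap
#'   matrix).
#' @param x a [DatedTree-class] containing all overlap taxa as tips.
#' @param statistic which overlap statistic to use, \code{"D"} or
#'   \code{"I"} (ignored when \code{overlap} is a single matrix).
#' @param nPermutations number of matrix relabelings (default 1000).
#' @param seed integer seed for the permutations.
#' @return list: \code{slope}, \code{intercept}, \code{adjusted_r2}
#'   (\eqn{1 - (1-r^2)(n-1)/(n-2)}), \code{p_value} (permutation),
#'   \code{p_parametric}, \code{n_pairs}, \code{n_permutations},
#'   \code{seed}.
#' @export
ageRangeCorrelation <- function(overlap, x, statistic = c("D", "I"),
                                nPermutations = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  m <- if (is.list(overlap) && !is.null(overlap[[statistic]]))
    overlap[[statistic]] else as.matrix(overlap)
  taxa <- rownames(m)
  ages <- mrcaAges(x, taxa)
  ut <- upper.tri(m)
  ageVec <- ages[ut]
  if (sum(ut) < 3L) stop("need at least 3 pairs")
  if (stats::var(ageVec) == 0)
    stop("all MRCA ages equal; slope undefined")

  slopeOf <- function(mm) {
    y <- mm[ut]
    stats::cov(ageVec, y) / stats::var(ageVec)
  }
  obs <- slopeOf(m)
  y <- m[ut]
  fit <- stats::lm(y ~ ageVec)
  sm <- suppressWarnings(summary(fit))   # a perfect fit is a valid input
  r2 <- sm$r.squared
  npairs <- length(y)
  adj <- 1 - (1 - r2) * (npairs - 1) / (npairs - 2)
  pPar <- stats::coef(sm)[2L, 4L]

  k <- nrow(m)
  exceed <- withSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPermutations)) {
      p <- sample.int(k)
      if (abs(slopeOf(m[p, p])) >= abs(obs)) cnt <- cnt + 1L
    }
    cnt
  })
  list(slope = obs, intercept = unname(stats::coef(fit)[1L]),
       adjusted_r2 = adj,
       p_value = (1 + exceed) / (1 + nPermutations),
       p_parametric = unname(pPar),
       n_pairs = npairs, n_permutations = nPermutations, seed = seed,
       statistic = statistic)
}
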