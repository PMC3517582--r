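## Dated-tree ingestion and node handling: ages, posterior-probability
## filtering, and matching nodes to the climate scenario closest in age.

#' Construct a dated tree from an ape phylo
#'
#' Computes node ages from branch lengths (tips at age 0 for ultrametric
#' trees) and pulls per-internal-node posterior probabilities from
#' \code{node.label} when the labels parse as numbers in \[0, 1\].
#' Polytomies, negative branch lengths and duplicate tip labels are
#' rejected; non-ultrametric trees are accepted with a warning, ages then
#' measured up from the deepest tip.
#'
#' @param tree an \code{ape::phylo}, rooted and binary, branch lengths in
#'   Ma.
#' @param ultrametricTol relative tolerance on root-to-tip path spread
#'   before the non-ultrametric warning fires (default 1e-6 of tree
#'   height).
#' @return a [DatedTree-class].
#' @export
datedTree <- function(tree, ultrametricTol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\"")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree contains polytomies; a fully resolved tree is required")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
  height <- max(depth[seq_len(n)])
  spread <- height - min(depth[seq_len(n)])
  if (height > 0 && spread > ultrametricTol * height)
    warning(sprintf(paste0("tree is not ultrametric (tip depth spread ",
                           "%.3g); node ages measured from the deepest tip"),
                    spread))
  ages <- height - depth
  pp <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    suppressWarnings(num <- as.numeric(tree$node.label))
    ok <- !is.na(num) & num >= 0 & num <= 1
    pp[ok] <- num[ok]
  }
  new("DatedTree", tree = tree, ages = ages, pp = pp)
}

#' Read a dated tree from a Newick file
#'
#' Internal node labels, when numeric in \[0, 1\], are interpreted as
#' posterior probabilities (the usual maximum-clade-credibility export).
#' Bracketed metadata comments (\code{[&...]}) are tolerated and ignored.
#'
#' @param path Newick file path.
#' @param ... passed to [datedTree()].
#' @return a [DatedTree-class].
#' @export
readDatedTree <- function(path, ...) {
  if (!file.exists(path)) stop("no such tree file: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\[&[^]]*\\]", "", txt)       # strip metadata comments
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  datedTree(tr, ...)
}

#' Write a dated tree to Newick
#'
#' @param x a [DatedTree-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDatedTree <- function(x, path) {
  stopifnot(is(x, "DatedTree"))
  ape::write.tree(x@tree, file = path)
  invisible(path)
}

#' Internal nodes above a posterior-probability cutoff
#'
#' Returns the ids of internal nodes whose posterior probability exceeds
#' \code{minPP} (strict).  Only for these well-supported nodes are
#' ancestral projections worth mapping.  A root without a recorded
#' posterior probability is included by convention (an MCC root is certain
#' by construction); any other unlabelled node is skipped.
#'
#' @param x a [DatedTree-class] with posterior probabilities.
#' @param minPP cutoff (default 0.95, strict inequality).
#' @return integer vector of node ids (ape numbering, root = nTips + 1).
#' @export
supportedNodes <- function(x, minPP = 0.95) {
  stopifnot(is(x, "DatedTree"))
  n <- nTips(x)
  ids <- seq_len(x@tree$Nnode) + n
  pass <- !is.na(x@pp) & x@pp > minPP
  pass[ids == n + 1L & is.na(x@pp)] <- TRUE   # unlabelled root
  ids[pass]
}

#' Match a node age to the closest climate scenario
#'
#' Chooses the scenario whose age is closest to the node's age; an exact
#' tie is broken towards the younger scenario.
#'
#' @param nodeAge node age in Ma.
#' @param scenarios list of [ClimateScenario-class] objects.
#' @return the chosen [ClimateScenario-class].
#' @export
assignScenario <- function(nodeAge, scenarios) {
  if (!length(scenarios)) stop("no scenarios supplied")
  ages <- vapply(scenarios, scenarioAge, numeric(1))
  d <- abs(ages - nodeAge)
  cand <- which(d == min(d))
  scenarios[[cand[which.min(ages[cand])]]]
}

#' Node table of a dated tree
#'
#' @param x a [DatedTree-class].
#' @return data frame with one row per node: \code{node_id}, \code{label}
#'   (tip label or ""), \code{age_ma}, \code{pp} (NA for tips), and the two
#'   child ids (\code{NA} for tips).
#' @export
nodeTable <- function(x) {
  stopifnot(is(x, "DatedTree"))
  tr <- x@tree
  n <- length(tr$tip.label)
  ids <- seq_len(n + tr$Nnode)
  kids <- lapply(ids, function(i) tr$edge[tr$edge[, 1L] == i, 2L])
  data.frame(
    node_id = ids,
    label = c(tr$tip.label, rep("", tr$Nnode)),
    age_ma = x@ages,
    pp = c(rep(NA_real_, n), x@pp),
    child1 = vapply(kids, function(k) if (length(k)) k[1L] else NA_integer_,
                    integer(1)),
    child2 = vapply(kids, function(k) if (length(k) > 1L) k[2L] else
      NA_integer_, integer(1))
  )
}

#' Pairwise MRCA ages for a set of tips
#'
#' @param x a [DatedTree-class].
#' @param taxa tip labels (default all tips).
#' @return symmetric matrix of MRCA ages in Ma, zero diagonal.
#' @export
mrcaAges <- function(x, taxa = NULL) {
  stopifnot(is(x, "DatedTree"))
  tr <- x@tree
  if (is.null(taxa)) taxa <- tr$tip.label
  miss <- setdiff(taxa, tr$tip.label)
  if (length(miss))
    stop("taxa not in tree: ", paste(miss, collapse = ", "))
  m <- ape::mrca(tr)[taxa, taxa, drop = FALSE]
  ages <- matrix(x@ages[m], nrow(m), ncol(m), dimnames = dimnames(m))
  diag(ages) <- 0
  ages
}
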