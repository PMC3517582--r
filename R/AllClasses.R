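#' @import methods
NULL

#' A single gridded climate variable
#'
#' One co-registerable raster layer holding a named climate variable on a
#' regular longitude/latitude grid.  Row 1 of the matrix is the northernmost
#' row, column 1 the westernmost column (the layout of an ESRI ASCII grid
#' read top-to-bottom).  Missing cells are stored as \code{NA}; the
#' \code{nodata} slot only records the sentinel used on disk.
#'
#' Temperatures are conventionally in degrees Celsius and precipitation in
#' millimetres per day, but no unit conversion is ever applied: values are
#' carried through envelopes and projections unchanged.
#'
#' @slot variable single character, the climate variable name.
#' @slot grid numeric matrix of cell values (\code{NA} = missing).
#' @slot xll longitude of the west edge (degrees, cell-registered corner).
#' @slot yll latitude of the south edge (degrees).
#' @slot cellsize cell width/height in decimal degrees (square cells).
#' @slot nodata numeric sentinel written to file for missing cells.
#'
#' @seealso [readAsciiGrid()], [ClimateScenario-class]
#' @export
setClass("ClimateLayer",
  representation(
    variable = "character",
    grid     = "matrix",
    xll      = "numeric",
    yll      = "numeric",
    cellsize = "numeric",
    nodata   = "numeric"
  ),
  prototype(nodata = -9999)
)

setValidity("ClimateLayer", function(object) {
  msg <- character()
  if (length(object@variable) != 1L || !nzchar(object@variable))
    msg <- c(msg, "'variable' must be a single non-empty string")
  if (!is.numeric(object@grid))
    msg <- c(msg, "'grid' must be a numeric matrix")
  if (length(object@cellsize) != 1L || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "'cellsize' must be a single positive number")
  if (length(object@xll) != 1L || length(object@yll) != 1L ||
      !all(is.finite(c(object@xll, object@yll))))
    msg <- c(msg, "'xll' and 'yll' must be single finite numbers")
  if (is.numeric(object@grid) && any(is.infinite(object@grid)))
    msg <- c(msg, "grid values must be finite or NA")
  if (length(msg)) msg else TRUE
})

#' A climate scenario: a stack of co-registered layers for one time slice
#'
#' Represents the climate of one time slice (present day or a paleoclimate
#' reconstruction) as an ordered stack of [ClimateLayer-class] objects that
#' all share origin, cell size and grid shape.  The \code{age} slot is the
#' age of the slice in million years before present (0 for present day).
#'
#' @slot name scenario label, e.g. \code{"present"} or \code{"10Ma"}.
#' @slot age age in Ma before present (non-negative).
#' @slot layers list of [ClimateLayer-class] objects with unique variable
#'   names, all co-registered.
#'
#' @seealso [readScenario()], [sampleValues()], [projectEnvelope()]
#' @export
setClass("ClimateScenario",
  representation(
    name   = "character",
    age    = "numeric",
    layers = "list"
  )
)

setValidity("ClimateScenario", function(object) {
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (length(object@age) != 1L || !is.finite(object@age) || object@age < 0)
    msg <- c(msg, "'age' must be a single non-negative number (Ma)")
  if (!all(vapply(object@layers, is, logical(1), "ClimateLayer")))
    msg <- c(msg, "'layers' must all be ClimateLayer objects")
  else if (length(object@layers)) {
    vars <- vapply(object@layers, function(l) l@variable, character(1))
    if (anyDuplicated(vars))
      msg <- c(msg, "duplicate variable names in scenario")
    ref <- object@layers[[1L]]
    for (l in object@layers[-1L]) {
      if (!identical(dim(l@grid), dim(ref@grid)) ||
          !isTRUE(all.equal(c(l@xll, l@yll, l@cellsize),
                            c(ref@xll, ref@yll, ref@cellsize))))
        msg <- c(msg, sprintf("layer '%s' is not co-registered with '%s'",
                              l@variable, ref@variable))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Georeferenced presence records for one species
#'
#' Presence-only occurrence points (decimal-degree longitude/latitude) for a
#' single species, with free-text provenance.  Cleaning (duplicate and
#' off-grid/no-data removal) is performed by [cleanOccurrences()], which
#' returns a new object plus a report; the class itself only enforces
#' coordinate sanity.
#'
#' @slot species species name.
#' @slot coords two-column numeric matrix (lon, lat) in decimal degrees.
#' @slot source free-text provenance (database, herbarium, "synthetic", ...).
#'
#' @export
setClass("OccurrenceSet",
  representation(
    species = "character",
    coords  = "matrix",
    source  = "character"
  ),
  prototype(source = "")
)

setValidity("OccurrenceSet", function(object) {
  msg <- character()
  if (length(object@species) != 1L || !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  cc <- object@coords
  if (!is.numeric(cc) || ncol(cc) != 2L)
    msg <- c(msg, "'coords' must be a numeric matrix with 2 columns (lon, lat)")
  else if (nrow(cc)) {
    if (any(!is.finite(cc)))
      msg <- c(msg, "coordinates must be finite")
    else if (any(cc[, 1L] < -180 | cc[, 1L] > 180 |
                 cc[, 2L] < -90  | cc[, 2L] > 90))
      msg <- c(msg, "coordinates outside [-180,180] x [-90,90]")
  }
  if (length(msg)) msg else TRUE
})

#' A min-max bioclimatic envelope
#'
#' The climate preferences of a taxon or tree node as one closed interval
#' \eqn{[min, max]} per climate variable, in the variable's own units.  For
#' extant taxa the bounds are the observed extremes over the occurrence
#' cells ([fitEnvelope()]); for internal nodes they are maximum-likelihood
#' Brownian-motion reconstructions ([reconstructEnvelopes()]).
#'
#' @slot taxon taxon or node identifier.
#' @slot variables climate variable names (unique, ordered).
#' @slot mins,maxs per-variable lower/upper bounds, \code{maxs >= mins}.
#' @slot nPoints number of occurrence points behind the fit (\code{NA} for
#'   reconstructed nodes).
#'
#' @seealso [projectEnvelope()], [envelopeBounds()]
#' @export
setClass("EnvelopeModel",
  representation(
    taxon     = "character",
    variables = "character",
    mins      = "numeric",
    maxs      = "numeric",
    nPoints   = "integer"
  ),
  prototype(nPoints = NA_integer_)
)

setValidity("EnvelopeModel", function(object) {
  msg <- character()
  k <- length(object@variables)
  if (length(object@taxon) != 1L)
    msg <- c(msg, "'taxon' must be a single string")
  if (k == 0L)
    msg <- c(msg, "envelope must cover at least one variable")
  if (anyDuplicated(object@variables))
    msg <- c(msg, "duplicate variable names in envelope")
  if (length(object@mins) != k || length(object@maxs) != k)
    msg <- c(msg, "'mins' and 'maxs' must match 'variables' in length")
  else if (any(!is.finite(object@mins)) || any(!is.finite(object@maxs)))
    msg <- c(msg, "envelope bounds must be finite")
  else if (any(object@maxs < object@mins))
    msg <- c(msg, "'maxs' must be >= 'mins' for every variable")
  if (length(msg)) msg else TRUE
})

#' A projected suitability surface
#'
#' The result of projecting an envelope into a scenario: per grid cell, the
#' fraction of climate variables whose value falls inside the envelope, so
#' every value is a multiple of \eqn{1/L} where \eqn{L} is the number of
#' variables scored.  Cells that are missing in any scored layer are
#' \code{NA}.
#'
#' @slot grid numeric matrix of suitability values in \{0, 1/L, ..., 1\}.
#' @slot nLayers the number of variables L.
#' @slot xll,yll,cellsize georeferencing, copied from the scenario.
#'
#' @seealso [projectEnvelope()], [classifySurface()], [overlapD()]
#' @export
setClass("SuitabilitySurface",
  representation(
    grid     = "matrix",
    nLayers  = "integer",
    xll      = "numeric",
    yll      = "numeric",
    cellsize = "numeric"
  )
)

setValidity("SuitabilitySurface", function(object) {
  msg <- character()
  L <- object@nLayers
  if (length(L) != 1L || is.na(L) || L < 1L)
    msg <- c(msg, "'nLayers' must be a positive integer")
  v <- object@grid[!is.na(object@grid)]
  if (length(v) && length(L) == 1L && !is.na(L) && L >= 1L) {
    if (any(v < 0 | v > 1))
      msg <- c(msg, "suitability values must lie in [0, 1]")
    k <- v * L
    if (any(abs(k - round(k)) > 1e-9))
      msg <- c(msg, "suitability values must be multiples of 1/nLayers")
  }
  if (length(msg)) msg else TRUE
})

#' A dated, fully resolved phylogeny
#'
#' Wraps an \pkg{ape} \code{phylo} tree whose branch lengths are in million
#' years, together with derived node ages (Ma before present) and optional
#' per-internal-node posterior probabilities (read from Newick internal node
#' labels, the common maximum-clade-credibility export convention).
#'
#' Node ids follow the \pkg{ape} convention: tips are 1..n in tip-label
#' order, internal nodes n+1..2n-1 with the root at n+1.  For an ultrametric
#' tree all tips have age 0; non-ultrametric trees are accepted with a
#' warning, ages then being measured from the deepest tip.
#'
#' @slot tree an \code{ape::phylo} object (rooted, binary).
#' @slot ages numeric vector of node ages in Ma, indexed by node id.
#' @slot pp numeric vector of posterior probabilities for internal nodes
#'   (indexed 1..Nnode, i.e. node id minus n tips); \code{NA} where absent.
#'
#' @seealso [readDatedTree()], [nodeAges()], [supportedNodes()]
#' @export
setClass("DatedTree",
  representation(
    tree = "ANY",
    ages = "numeric",
    pp   = "numeric"
  )
)

setValidity("DatedTree", function(object) {
  msg <- character()
  tr <- object@tree
  if (!inherits(tr, "phylo"))
    msg <- c(msg, "'tree' must be an ape \"phylo\" object")
  else {
    n <- length(tr$tip.label)
    if (anyDuplicated(tr$tip.label))
      msg <- c(msg, "duplicate tip labels")
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
      msg <- c(msg, "negative branch lengths")
    if (length(object@ages) != n + tr$Nnode)
      msg <- c(msg, "'ages' must have one entry per node")
    if (length(object@pp) != tr$Nnode)
      msg <- c(msg, "'pp' must have one entry per internal node")
  }
  if (length(msg)) msg else TRUE
})
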