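## Generics and accessors for the core classes.  Slot access from user code
## should always go through these.

#' Variable names of a scenario or envelope
#' @param x a [ClimateScenario-class] or [EnvelopeModel-class].
#' @return character vector of climate variable names, in storage order.
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname variableNames
#' @export
setMethod("variableNames", "ClimateScenario", function(x)
  vapply(x@layers, function(l) l@variable, character(1)))

#' @rdname variableNames
#' @export
setMethod("variableNames", "EnvelopeModel", function(x) x@variables)

#' Grid dimensions (rows, cols)
#' @param x a [ClimateScenario-class], [ClimateLayer-class] or
#'   [SuitabilitySurface-class].
#' @return integer vector \code{c(nrow, ncol)}.
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridDim
#' @export
setMethod("gridDim", "ClimateLayer", function(x) dim(x@grid))

#' @rdname gridDim
#' @export
setMethod("gridDim", "ClimateScenario", function(x) {
  if (!length(x@layers)) stop("empty scenario")
  dim(x@layers[[1L]]@grid)
})

#' @rdname gridDim
#' @export
setMethod("gridDim", "SuitabilitySurface", function(x) dim(x@grid))

#' Scenario name and age
#' @param x a [ClimateScenario-class].
#' @return the scenario label (character) / age in Ma (numeric).
#' @export
setGeneric("scenarioName", function(x) standardGeneric("scenarioName"))

#' @rdname scenarioName
#' @export
setMethod("scenarioName", "ClimateScenario", function(x) x@name)

#' @rdname scenarioName
#' @export
setGeneric("scenarioAge", function(x) standardGeneric("scenarioAge"))

#' @rdname scenarioName
#' @export
setMethod("scenarioAge", "ClimateScenario", function(x) x@age)

#' Extract one layer from a scenario
#' @param x a [ClimateScenario-class].
#' @param variable a variable name present in the scenario.
#' @return the matching [ClimateLayer-class].
#' @export
setGeneric("getLayer", function(x, variable) standardGeneric("getLayer"))

#' @rdname getLayer
#' @export
setMethod("getLayer", "ClimateScenario", function(x, variable) {
  i <- match(variable, variableNames(x))
  if (is.na(i))
    stop(sprintf("variable '%s' not present in scenario '%s'",
                 variable, x@name))
  x@layers[[i]]
})

#' Raw value matrix of a layer or surface
#' @param x a [ClimateLayer-class] or [SuitabilitySurface-class].
#' @return numeric matrix (row 1 = northernmost row; \code{NA} = missing).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridValues
#' @export
setMethod("gridValues", "ClimateLayer", function(x) x@grid)

#' @rdname gridValues
#' @export
setMethod("gridValues", "SuitabilitySurface", function(x) x@grid)

#' Number of layers scored into a suitability surface
#' @param x a [SuitabilitySurface-class].
#' @return integer L: surface values are multiples of 1/L.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname nLayers
#' @export
setMethod("nLayers", "SuitabilitySurface", function(x) x@nLayers)

#' Occurrence accessors
#' @param x an [OccurrenceSet-class].
#' @return \code{occurrenceCoords}: two-column matrix (lon, lat);
#'   \code{nOccurrences}: integer count; \code{speciesName}: the species.
#' @export
setGeneric("occurrenceCoords", function(x) standardGeneric("occurrenceCoords"))

#' @rdname occurrenceCoords
#' @export
setMethod("occurrenceCoords", "OccurrenceSet", function(x) x@coords)

#' @rdname occurrenceCoords
#' @export
setGeneric("nOccurrences", function(x) standardGeneric("nOccurrences"))

#' @rdname occurrenceCoords
#' @export
setMethod("nOccurrences", "OccurrenceSet", function(x) nrow(x@coords))

#' @rdname occurrenceCoords
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname occurrenceCoords
#' @export
setMethod("speciesName", "OccurrenceSet", function(x) x@species)

#' Envelope accessors
#' @param x an [EnvelopeModel-class].
#' @return \code{envelopeBounds}: data frame with columns
#'   \code{variable}, \code{min}, \code{max}; \code{taxonName}: identifier;
#'   \code{nPoints}: occurrence points behind the fit (NA if reconstructed).
#' @export
setGeneric("envelopeBounds", function(x) standardGeneric("envelopeBounds"))

#' @rdname envelopeBounds
#' @export
setMethod("envelopeBounds", "EnvelopeModel", function(x)
  data.frame(variable = x@variables, min = x@mins, max = x@maxs))

#' @rdname envelopeBounds
#' @export
setGeneric("taxonName", function(x) standardGeneric("taxonName"))

#' @rdname envelopeBounds
#' @export
setMethod("taxonName", "EnvelopeModel", function(x) x@taxon)

#' @rdname envelopeBounds
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname envelopeBounds
#' @export
setMethod("nPoints", "EnvelopeModel", function(x) x@nPoints)

#' Dated-tree accessors
#' @param x a [DatedTree-class].
#' @return \code{apeTree}: the underlying \code{phylo}; \code{nodeAges}:
#'   ages in Ma indexed by node id; \code{posteriorProbs}: per-internal-node
#'   posterior probabilities named by node id; \code{nTips}: tip count.
#' @export
setGeneric("apeTree", function(x) standardGeneric("apeTree"))

#' @rdname apeTree
#' @export
setMethod("apeTree", "DatedTree", function(x) x@tree)

#' @rdname apeTree
#' @export
setGeneric("nodeAges", function(x) standardGeneric("nodeAges"))

#' @rdname apeTree
#' @export
setMethod("nodeAges", "DatedTree", function(x) x@ages)

#' @rdname apeTree
#' @export
setGeneric("posteriorProbs", function(x) standardGeneric("posteriorProbs"))

#' @rdname apeTree
#' @export
setMethod("posteriorProbs", "DatedTree", function(x) {
  n <- length(x@tree$tip.label)
  stats::setNames(x@pp, seq_len(x@tree$Nnode) + n)
})

#' @rdname apeTree
#' @export
setGeneric("nTips", function(x) standardGeneric("nTips"))

#' @rdname apeTree
#' @export
setMethod("nTips", "DatedTree", function(x) length(x@tree$tip.label))

## ---- show methods -------------------------------------------------------

setMethod("show", "ClimateLayer", function(object) {
  d <- dim(object@grid)
  cat(sprintf("ClimateLayer '%s': %d x %d cells @ %g deg, origin (%g, %g), %d missing\n",
              object@variable, d[1L], d[2L], object@cellsize,
              object@xll, object@yll, sum(is.na(object@grid))))
})

setMethod("show", "ClimateScenario", function(object) {
  cat(sprintf("ClimateScenario '%s' (%g Ma): %d layer(s)\n",
              object@name, object@age, length(object@layers)))
  if (length(object@layers)) {
    d <- gridDim(object)
    cat(sprintf("  grid %d x %d @ %g deg, origin (%g, %g)\n",
                d[1L], d[2L], object@layers[[1L]]@cellsize,
                object@layers[[1L]]@xll, object@layers[[1L]]@yll))
    cat("  variables:", paste(variableNames(object), collapse = ", "), "\n")
  }
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s': %d point(s)%s\n", object@species,
              nrow(object@coords),
              if (nzchar(object@source)) paste0(" [", object@source, "]") else ""))
})

setMethod("show", "EnvelopeModel", function(object) {
  cat(sprintf("EnvelopeModel '%s' (%s point(s)):\n", object@taxon,
              ifelse(is.na(object@nPoints), "NA", object@nPoints)))
  print(envelopeBounds(object), row.names = FALSE)
})

setMethod("show", "SuitabilitySurface", function(object) {
  d <- dim(object@grid)
  ok <- !is.na(object@grid)
  cat(sprintf("SuitabilitySurface: %d x %d cells, L = %d, %d masked\n",
              d[1L], d[2L], object@nLayers, sum(!ok)))
  if (any(ok))
    cat(sprintf("  suitable (==1): %d cell(s); mean suitability %.3f\n",
                sum(object@grid[ok] == 1), mean(object@grid[ok])))
})

setMethod("show", "DatedTree", function(object) {
  tr <- object@tree
  n <- length(tr$tip.label)
  cat(sprintf("DatedTree: %d tips, root age %.3f Ma, %d/%d internal nodes with pp\n",
              n, object@ages[n + 1L], sum(!is.na(object@pp)), tr$Nnode))
})
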