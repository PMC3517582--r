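## The envelope-score algorithm: min-max envelopes from sampled climate
## values, projection into scenarios, surface classification, and the
## environmentally-unique-point count used to qualify species for the
## variable-selection stage.

#' Construct an envelope model directly from bounds
#'
#' @param taxon taxon or node identifier.
#' @param variables climate variable names.
#' @param mins,maxs per-variable bounds (closed intervals, `maxs >= mins`).
#' @param nPoints number of occurrence points behind the fit, if any.
#' @return an [EnvelopeModel-class].
#' @export
envelopeModel <- function(taxon, variables, mins, maxs,
                          nPoints = NA_integer_) {
  new("EnvelopeModel", taxon = taxon, variables = as.character(variables),
      mins = as.numeric(mins), maxs = as.numeric(maxs),
      nPoints = as.integer(nPoints))
}

#' Fit a min-max climate envelope
#'
#' The envelope of a taxon is, per climate variable, the closed interval
#' between the smallest and largest value observed at its valid occurrence
#' points.  Intervals may be degenerate (\code{min == max}) when all points
#' share one climate cell; such minimal models are fitted as-is rather than
#' widened, which is the appropriate treatment for narrow endemics known
#' from a single climatic niche.  A warning is issued when fewer than
#' \code{warnBelow} points support the fit.
#'
#' @param valuesTable output of [sampleValues()]; only rows with
#'   \code{valid == TRUE} contribute.
#' @param taxon identifier to attach to the model.
#' @param variables which variable columns to use; defaults to every
#'   variable column present.
#' @param warnBelow warn when the number of valid points is below this
#'   (default 10, the usual rule of thumb for presence-only models).
#' @return an [EnvelopeModel-class].
#' @export
fitEnvelope <- function(valuesTable, taxon, variables = NULL,
                        warnBelow = 10L) {
  vars <- envVarColumns(valuesTable, variables)
  tab <- valuesTable[valuesTable$valid, vars, drop = FALSE]
  if (!nrow(tab))
    stop("cannot fit envelope for '", taxon, "': no valid points")
  if (nrow(tab) < warnBelow)
    warning(sprintf("envelope for '%s' fitted from only %d point(s)",
                    taxon, nrow(tab)))
  envelopeModel(taxon, vars,
                mins = vapply(tab, min, numeric(1)),
                maxs = vapply(tab, max, numeric(1)),
                nPoints = nrow(tab))
}

envVarColumns <- function(valuesTable, variables = NULL) {
  meta <- c("lon", "lat", "row", "col", "valid")
  vars <- setdiff(names(valuesTable), meta)
  if (!is.null(variables)) {
    missing <- setdiff(variables, vars)
    if (length(missing))
      stop("variables not present in values table: ",
           paste(missing, collapse = ", "))
    vars <- variables
  }
  if (!length(vars)) stop("values table has no variable columns")
  vars
}

#' Project an envelope into a climate scenario
#'
#' Scores every grid cell by the number of climate variables whose value
#' lies inside the envelope's closed interval, divided by the number of
#' variables L, giving a suitability in \{0, 1/L, ..., 1\}.  Cells missing
#' in any scored layer are masked (\code{NA}).
#'
#' @param model an [EnvelopeModel-class]; every model variable must exist in
#'   the scenario.
#' @param scenario a [ClimateScenario-class].
#' @return a [SuitabilitySurface-class] on the scenario's native grid.
#' @export
projectEnvelope <- function(model, scenario) {
  stopifnot(is(model, "EnvelopeModel"), is(scenario, "ClimateScenario"))
  missing <- setdiff(model@variables, variableNames(scenario))
  if (length(missing))
    stop("scenario '", scenario@name, "' lacks model variable(s): ",
         paste(missing, collapse = ", "))
  ref <- scenario@layers[[1L]]
  L <- length(model@variables)
  count <- matrix(0, nrow(ref@grid), ncol(ref@grid))
  mask <- matrix(FALSE, nrow(ref@grid), ncol(ref@grid))
  for (i in seq_len(L)) {
    g <- getLayer(scenario, model@variables[i])@grid
    mask <- mask | is.na(g)
    count <- count + (!is.na(g) & g >= model@mins[i] & g <= model@maxs[i])
  }
  s <- count / L
  s[mask] <- NA_real_
  new("SuitabilitySurface", grid = s, nLayers = as.integer(L),
      xll = ref@xll, yll = ref@yll, cellsize = ref@cellsize)
}

#' Classify a suitability surface
#'
#' Three-way classification used when mapping projections: code 2 ("red")
#' for cells suitable by all L variables, code 1 ("yellow") for cells
#' suitable by exactly L-1 of them, code 0 for everything below.  With a
#' single-variable model (L = 1) only the codes 2 and 0 occur.  Masked
#' cells stay \code{NA}.
#'
#' @param surface a [SuitabilitySurface-class].
#' @return integer matrix of codes 0/1/2 with \code{NA} for masked cells.
#' @export
classifySurface <- function(surface) {
  stopifnot(is(surface, "SuitabilitySurface"))
  L <- surface@nLayers
  g <- surface@grid
  out <- matrix(NA_integer_, nrow(g), ncol(g))
  ok <- !is.na(g)
  k <- round(g[ok] * L)
  out[ok] <- ifelse(k == L, 2L, ifelse(L > 1L & k == L - 1L, 1L, 0L))
  out
}

#' Count environmentally unique occurrence points
#'
#' An occurrence point is environmentally unique if its vector of climate
#' values (over the modelled variables, read at cell resolution) has not
#' been contributed by an earlier point of the same species; the count is
#' therefore the number of distinct climate-value vectors among the valid
#' points.  Species need a minimum number of unique points (conventionally
#' ten) to qualify for the mean-AUC table behind variable selection.
#'
#' @param valuesTable output of [sampleValues()].
#' @param variables variable columns to compare on; default all.
#' @return integer count of distinct climate-value vectors.
#' @export
countEnvUnique <- function(valuesTable, variables = NULL) {
  vars <- envVarColumns(valuesTable, variables)
  tab <- valuesTable[valuesTable$valid, vars, drop = FALSE]
  if (!nrow(tab)) return(0L)
  key <- do.call(paste, c(lapply(tab, formatExact), sep = "\r"))
  length(unique(key))
}

#' Read / write envelope tables
#'
#' Envelope tables are long-format CSVs with columns
#' \code{taxon,variable,min,max,n_points}: one row per taxon-variable pair,
#' the layout in which per-taxon and per-node bounds are published.
#'
#' @param path CSV path.
#' @return \code{readEnvelopes}: named list of [EnvelopeModel-class].
#' @export
readEnvelopes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "variable", "min", "max")
  if (!all(need %in% names(df)))
    stop("envelope CSV must have columns taxon, variable, min, max")
  taxa <- unique(df$taxon)
  out <- lapply(taxa, function(tx) {
    i <- df$taxon == tx
    np <- if ("n_points" %in% names(df)) df$n_points[i][1L] else NA_integer_
    envelopeModel(as.character(tx), df$variable[i], df$min[i], df$max[i],
                  nPoints = np)
  })
  stats::setNames(out, taxa)
}

#' @rdname readEnvelopes
#' @param envList a single [EnvelopeModel-class] or list of them.
#' @return \code{writeEnvelopes}: \code{path}, invisibly.
#' @export
writeEnvelopes <- function(envList, path) {
  if (is(envList, "EnvelopeModel")) envList <- list(envList)
  rows <- lapply(envList, function(e)
    data.frame(taxon = e@taxon, variable = e@variables,
               min = e@mins, max = e@maxs, n_points = e@nPoints))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
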