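## Published reference tables for the ivesioid clade of Potentilla
## (genera Ivesia, Horkelia, Horkeliella), shipped as plain-text fixtures:
## per-species envelope bounds for the four modelling variables, ancestral
## bounds for the internal nodes of the clade's dated phylogeny, and the
## per-variable mean AUC / correlation table from which the four variables
## were selected.  Used as realistic-shaped inputs in examples and
## regression tests; the occurrence records, climate grids and chronogram
## behind them are not redistributable, so values are consumed as given.

fixturePath <- function(name)
  system.file("extdata", name, package = "paleoniche", mustWork = TRUE)

#' Published tip envelope bounds for the ivesioid clade
#'
#' Min-max envelope bounds of the 38 ivesioid species plus their sister
#' species \emph{Potentilla biennis} over the four selected climate
#' variables (temperatures in degrees C, precipitation in mm/day), with the
#' number of occurrence records behind each fit.
#'
#' @return list with \code{table} (wide data frame, one row per species)
#'   and \code{models} (named list of [EnvelopeModel-class]).
#' @export
ivesioidTipEnvelopes <- function() {
  df <- utils::read.csv(fixturePath("ivesioid_tip_envelopes.csv"),
                        check.names = FALSE)
  vars <- boundsTableVariables(df)
  models <- lapply(seq_len(nrow(df)), function(i)
    envelopeModel(df$species[i], vars,
                  mins = as.numeric(df[i, paste0(vars, "_min")]),
                  maxs = as.numeric(df[i, paste0(vars, "_max")]),
                  nPoints = df$n_locations[i]))
  names(models) <- df$species
  list(table = df, models = models)
}

#' Published ancestral envelope bounds for the ivesioid clade
#'
#' Reconstructed per-node bounds for the internal nodes (numbered 40-77 in
#' the source figure's convention) of the clade's dated phylogeny, same
#' variables and units as [ivesioidTipEnvelopes()].  Intended as a
#' shape/sanity fixture: the chronogram's branch lengths were never
#' published numerically, so these values cannot be recomputed, only
#' checked for plausibility.
#'
#' @return wide data frame, one row per node.
#' @export
ivesioidAncestralBounds <- function() {
  utils::read.csv(fixturePath("ivesioid_ancestral_bounds.csv"),
                  check.names = FALSE)
}

#' Published per-variable mean AUC and correlation table
#'
#' The sixteen candidate climate variables with their mean single-variable
#' AUC over qualifying species, the flag marking the four variables kept
#' for the final models, and the full 16 x 16 Pearson correlation matrix
#' (mirrored from the published lower triangle).
#'
#' @return list with \code{auc} (data frame: \code{index}, \code{variable},
#'   \code{mean_auc}, \code{selected}) and \code{correlation} (symmetric
#'   matrix).
#' @export
climateVariableTable <- function() {
  auc <- utils::read.csv(fixturePath("climate_variable_auc.csv"),
                         check.names = FALSE)
  m <- utils::read.csv(fixturePath("climate_variable_correlations.csv"),
                       check.names = FALSE)
  corr <- as.matrix(m[, -1L])
  rownames(corr) <- m$variable
  list(auc = auc, correlation = corr)
}

boundsTableVariables <- function(df) {
  maxCols <- grep("_max$", names(df), value = TRUE)
  sub("_max$", "", maxCols)
}

#' Read a wide bounds table back into envelope models
#'
#' Inverse of [writeBoundsTable()]: parses a CSV with a taxon column and
#' per-variable \code{<variable>_max} / \code{<variable>_min} columns.
#'
#' @param path CSV path.
#' @param taxonColumn name of the identifier column (default first column).
#' @return named list of [EnvelopeModel-class].
#' @export
readBoundsTable <- function(path, taxonColumn = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (is.null(taxonColumn)) taxonColumn <- names(df)[1L]
  vars <- boundsTableVariables(df)
  if (!length(vars)) stop("no <variable>_max columns in ", path)
  models <- lapply(seq_len(nrow(df)), function(i)
    envelopeModel(as.character(df[[taxonColumn]][i]), vars,
                  mins = as.numeric(df[i, paste0(vars, "_min")]),
                  maxs = as.numeric(df[i, paste0(vars, "_max")]),
                  nPoints = if ("n_points" %in% names(df))
                    df$n_points[i] else NA_integer_))
  stats::setNames(models, as.character(df[[taxonColumn]]))
}
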