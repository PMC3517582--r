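## AUC evaluation of envelope models against presence points and sampled
## background cells, and the per-variable mean-AUC table that feeds variable
## selection.

## Run expr under a given seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample background (pseudo-absence) cells
#'
#' Draws a uniform random sample, without replacement, of grid cells that
#' are not missing in any layer of the scenario and are not excluded (the
#' presence cells).  Presence-only evaluation needs such background cells
#' in place of true absences.  If fewer eligible cells exist than requested,
#' all of them are returned with a warning.
#'
#' @param scenario a [ClimateScenario-class].
#' @param excludeCells integer vector of linear cell indices
#'   (column-major, \code{row + (col-1)*nrow}) to exclude.
#' @param n number of cells to draw.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return data frame with columns \code{cell}, \code{row}, \code{col}.
#' @export
sampleBackground <- function(scenario, excludeCells = integer(), n,
                             seed = 1L) {
  stopifnot(is(scenario, "ClimateScenario"))
  d <- gridDim(scenario)
  ok <- !is.na(scenario@layers[[1L]]@grid)
  for (l in scenario@layers[-1L]) ok <- ok & !is.na(l@grid)
  eligible <- setdiff(which(ok), excludeCells)
  if (length(eligible) < n) {
    warning(sprintf("only %d eligible background cells (%d requested)",
                    length(eligible), n))
    n <- length(eligible)
  }
  cells <- if (n == 0L) integer() else
    withSeed(seed, sample(eligible, n, replace = FALSE))
  data.frame(cell = cells,
             row = ((cells - 1L) %% d[1L]) + 1L,
             col = ((cells - 1L) %/% d[1L]) + 1L)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the proportion of presence-background score pairs in which the presence
#' scores higher, ties counting one half.  Equivalent to the trapezoidal
#' area under the ROC curve.  A value of 1 is perfect discrimination; 0.5
#' is no better than random.  The half-credit tie convention matters here
#' because envelope surfaces take at most L+1 distinct values.
#'
#' @param presenceScores,backgroundScores non-empty numeric vectors of model
#'   scores at presence cells and background cells.
#' @return AUC in \[0, 1\].
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores); nb <- length(backgroundScores)
  if (np == 0L || nb == 0L)
    stop("aucScore needs non-empty presence and background scores")
  if (anyNA(presenceScores) || anyNA(backgroundScores))
    stop("scores must not contain NA")
  r <- rank(c(presenceScores, backgroundScores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Evaluate an envelope model by AUC
#'
#' Projects the model into the scenario, scores the distinct presence cells
#' of the (cleaned) occurrences and a seeded uniform background sample, and
#' returns the rank-statistic AUC together with the environmentally-unique
#' point count for the modelled variables.  Duplicate presence cells
#' collapse to one, consistent with the unique-point logic.
#'
#' @param model an [EnvelopeModel-class].
#' @param occ an [OccurrenceSet-class], cleaned against \code{scenario}.
#' @param scenario a [ClimateScenario-class].
#' @param nBackground number of background cells; default
#'   \code{min(10 * n_presence_cells, 10000)}.
#' @param seed integer seed for the background draw.
#' @return one-row data frame: \code{taxon}, \code{variable_set},
#'   \code{auc}, \code{n_presence}, \code{n_background}, \code{n_env_unique},
#'   \code{seed}.
#' @export
evaluateModel <- function(model, occ, scenario, nBackground = NULL,
                          seed = 1L) {
  stopifnot(is(model, "EnvelopeModel"), is(occ, "OccurrenceSet"))
  sv <- sampleValues(scenario, occ)
  sv <- sv[sv$valid, , drop = FALSE]
  if (!nrow(sv))
    stop("no valid presence cells for '", model@taxon, "'")
  d <- gridDim(scenario)
  cells <- unique(sv$row + (sv$col - 1L) * d[1L])
  if (is.null(nBackground))
    nBackground <- min(10L * length(cells), 10000L)
  surf <- projectEnvelope(model, scenario)
  bg <- sampleBackground(scenario, excludeCells = cells, n = nBackground,
                         seed = seed)
  if (!nrow(bg))
    stop("no background cells available for '", model@taxon, "'")
  pres <- surf@grid[cells]
  back <- surf@grid[bg$cell]
  data.frame(
    taxon = model@taxon,
    variable_set = paste(model@variables, collapse = "+"),
    auc = aucScore(pres, back),
    n_presence = length(cells),
    n_background = nrow(bg),
    n_env_unique = countEnvUnique(sv, variables = model@variables),
    seed = seed
  )
}

#' Per-variable mean AUC over qualifying species
#'
#' For each climate variable, fits a single-variable envelope for every
#' species, evaluates it by AUC against seeded background, and averages the
#' AUCs over the species whose analysis has at least \code{minUnique}
#' environmentally unique points (uniqueness judged on that variable at cell
#' resolution).  Species below the cutoff are still modelled and reported,
#' but do not contribute to the mean.
#'
#' @param occList named list of cleaned [OccurrenceSet-class] objects.
#' @param scenario the [ClimateScenario-class] to model against.
#' @param variables variables to score; default all scenario variables.
#' @param minUnique qualification threshold on unique points (default 10).
#' @param nBackground per-evaluation background size; see [evaluateModel()].
#' @param seed integer seed; each species-variable evaluation derives its
#'   own sub-seed from it, so the whole table is reproducible.
#' @return list with \code{table} (data frame \code{variable},
#'   \code{mean_auc}, \code{n_species_used}) and \code{detail} (per
#'   species-variable evaluation rows, with \code{qualifies}).
#' @export
meanAucPerVariable <- function(occList, scenario, variables = NULL,
                               minUnique = 10L, nBackground = NULL,
                               seed = 1L) {
  if (is.null(variables)) variables <- variableNames(scenario)
  if (!length(occList)) stop("no species supplied")
  detail <- list()
  k <- 0L
  for (v in variables) {
    for (s in names(occList)) {
      k <- k + 1L
      sv <- sampleValues(scenario, occList[[s]])
      if (!any(sv$valid)) next
      mod <- suppressWarnings(
        fitEnvelope(sv, taxon = s, variables = v))
      row <- evaluateModel(mod, occList[[s]], scenario,
                           nBackground = nBackground,
                           seed = subSeed(seed, k))
      row$qualifies <- row$n_env_unique >= minUnique
      detail[[k]] <- row
    }
  }
  detail <- do.call(rbind, detail)
  tab <- do.call(rbind, lapply(variables, function(v) {
    rows <- detail[detail$variable_set == v & detail$qualifies, ,
                   drop = FALSE]
    if (!nrow(rows))
      warning("no species qualifies for variable '", v, "'")
    data.frame(variable = v,
               mean_auc = if (nrow(rows)) mean(rows$auc) else NA_real_,
               n_species_used = nrow(rows))
  }))
  list(table = tab, detail = detail)
}

## Deterministic sub-seed derivation: one user-facing seed fans out to the
## independent draws of a multi-evaluation run.  Kept below 2^31.
subSeed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1664525 * as.numeric(k)) %% 2147483647
}
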