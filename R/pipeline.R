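## Orchestration of the full analysis: variable selection -> tip envelopes
## -> ancestral reconstruction -> projections -> overlap and age-range
## correlation, with per-stage artifacts and a reproducibility manifest.

#' Run the phyloclimatic pipeline
#'
#' Executes the stages of the analysis in order, writing per-stage
#' artifacts into \code{output_dir} (when given) and returning everything
#' as a list.  Any stage error aborts with a stage-tagged message; the
#' artifacts of completed stages are retained on disk.
#'
#' The configuration is a named list (or the path of a YAML file holding
#' one) with entries:
#' \describe{
#'   \item{scenarios}{character vector of scenario manifest paths, or a
#'     list of [ClimateScenario-class]; the youngest scenario is used as
#'     present day.}
#'   \item{occurrences}{occurrence CSV path or named list of
#'     [OccurrenceSet-class].}
#'   \item{tree}{Newick path or [DatedTree-class].}
#'   \item{variables}{optional: pre-specified climate variables.  When set,
#'     the mean-AUC and selection stages are skipped and logged as
#'     skipped.}
#'   \item{selection}{list(threshold = 0.8, use_absolute = TRUE,
#'     order = "highest_r_first", tie_break = "keep_first_listed").}
#'   \item{evaluation}{list(n_background = NULL, min_unique = 10).}
#'   \item{min_pp}{posterior-probability cutoff for projected nodes
#'     (default 0.95).}
#'   \item{arc}{list(n_permutations = 1000, statistic = "D").}
#'   \item{seed}{mandatory integer seed driving every random draw.}
#'   \item{output_dir}{artifact directory; omit to skip writing.}
#' }
#'
#' @param config configuration list or YAML path.
#' @return list with elements \code{cleaning}, \code{mean_auc},
#'   \code{correlation}, \code{selection}, \code{variables},
#'   \code{tip_envelopes}, \code{tip_auc}, \code{reconstruction},
#'   \code{node_projections}, \code{tip_surfaces}, \code{overlap},
#'   \code{overlap_summary}, \code{arc}, \code{log}, \code{manifest}.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  outdir <- config$output_dir
  if (!is.null(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    message("[paleoniche] ", line)
    logLines <<- c(logLines, line)
    if (!is.null(outdir))
      writeLines(logLines, file.path(outdir, "pipeline_log.txt"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  saveCsv <- function(df, name) {
    if (!is.null(outdir))
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
  }
  res <- list()

  ## -- load ---------------------------------------------------------------
  stage("load", {
    scen <- config$scenarios
    if (is.character(scen)) scen <- lapply(scen, readScenario)
    if (is(scen, "ClimateScenario")) scen <- list(scen)
    if (!length(scen)) stop("no scenarios")
    ages <- vapply(scen, scenarioAge, numeric(1))
    present <- scen[[which.min(ages)]]
    occ <- config$occurrences
    if (is.character(occ)) occ <- readOccurrences(occ)
    tree <- config$tree
    if (is.character(tree)) tree <- readDatedTree(tree)
    res$scenarios <- scen
    res$present <- present
    res$tree <- tree
    res$occ_raw <- occ
    note("loaded %d scenario(s), %d species, tree with %d tips",
         length(scen), length(occ), nTips(tree))
  })

  ## -- clean --------------------------------------------------------------
  stage("clean", {
    cleaned <- lapply(res$occ_raw, cleanOccurrences, scenario = res$present)
    res$occ <- lapply(cleaned, `[[`, "occurrences")
    res$cleaning <- do.call(rbind, lapply(cleaned, `[[`, "report"))
    empty <- vapply(res$occ, nOccurrences, integer(1)) == 0L
    if (any(empty)) {
      note("dropping %d species with no valid occurrences: %s",
           sum(empty), paste(names(res$occ)[empty], collapse = ", "))
      res$occ <- res$occ[!empty]
    }
    saveCsv(res$cleaning, "cleaning_report.csv")
    note("cleaned occurrences: %d duplicates and %d invalid points removed",
         sum(res$cleaning$n_duplicate), sum(res$cleaning$n_invalid))
  })

  ## -- variable selection -------------------------------------------------
  if (!is.null(config$variables)) {
    res$variables <- config$variables
    res$mean_auc <- NULL
    note("variable selection skipped: %d pre-specified variable(s): %s",
         length(res$variables), paste(res$variables, collapse = ", "))
  } else {
    selCfg <- config$selection
    evalCfg <- config$evaluation
    minUnique <- if (is.null(evalCfg$min_unique)) 10L else
      as.integer(evalCfg$min_unique)
    stage("mean_auc", {
      ma <- meanAucPerVariable(res$occ, res$present,
                               minUnique = minUnique,
                               nBackground = evalCfg$n_background,
                               seed = seed)
      res$mean_auc <- ma$table
      res$mean_auc_detail <- ma$detail
      saveCsv(ma$table, "mean_auc.csv")
      saveCsv(ma$detail, "mean_auc_detail.csv")
      nLow <- length(unique(ma$detail$taxon[!ma$detail$qualifies]))
      note("mean AUC over %d variables; %d species below %d unique points in >=1 analysis",
           nrow(ma$table), nLow, minUnique)
    })
    stage("select_variables", {
      pooled <- do.call(rbind, lapply(res$occ, sampleValues,
                                      scenario = res$present))
      corr <- correlationMatrix(pooled)
      res$correlation <- corr
      if (!is.null(outdir))
        utils::write.csv(corr, file.path(outdir, "correlation.csv"))
      sel <- selectVariables(
        corr, res$mean_auc,
        threshold = if (is.null(selCfg$threshold)) 0.8 else selCfg$threshold,
        useAbsolute = !isFALSE(selCfg$use_absolute),
        order = if (is.null(selCfg$order)) "highest_r_first" else
          selCfg$order,
        tieBreak = if (is.null(selCfg$tie_break)) "keep_first_listed" else
          selCfg$tie_break)
      res$selection <- sel
      res$variables <- sel$retained
      if (!is.null(outdir))
        writeSelectionLog(sel, file.path(outdir, "selection_log.txt"))
      saveCsv(sel$log, "selection_exclusions.csv")
      note("retained %d of %d variables: %s", length(sel$retained),
           nrow(corr), paste(sel$retained, collapse = ", "))
    })
  }

  ## -- tip envelopes ------------------------------------------------------
  stage("tip_envelopes", {
    envs <- list()
    nSmall <- 0L
    for (s in names(res$occ)) {
      sv <- sampleValues(res$present, res$occ[[s]])
      envs[[s]] <- withCallingHandlers(
        fitEnvelope(sv, taxon = s, variables = res$variables),
        warning = function(w) {
          nSmall <<- nSmall + 1L
          invokeRestart("muffleWarning")
        })
    }
    res$tip_envelopes <- envs
    if (!is.null(outdir)) {
      writeEnvelopes(envs, file.path(outdir, "tip_envelopes.csv"))
      writeBoundsTable(envs, file.path(outdir, "tip_bounds_table.csv"))
    }
    note("fitted %d tip envelopes on %d variable(s); %d below 10 points",
         length(envs), length(res$variables), nSmall)
  })

  ## -- tip model evaluation ----------------------------------------------
  stage("tip_auc", {
    rows <- lapply(seq_along(res$tip_envelopes), function(i)
      evaluateModel(res$tip_envelopes[[i]],
                    res$occ[[taxonName(res$tip_envelopes[[i]])]],
                    res$present,
                    nBackground = config$evaluation$n_background,
                    seed = subSeed(seed, 5000L + i)))
    res$tip_auc <- do.call(rbind, rows)
    saveCsv(res$tip_auc, "tip_auc.csv")
    note("tip model AUC: mean %.3f over %d species",
         mean(res$tip_auc$auc), nrow(res$tip_auc))
  })

  ## -- ancestral reconstruction -------------------------------------------
  stage("reconstruct", {
    tips <- apeTree(res$tree)$tip.label
    missing <- setdiff(tips, names(res$tip_envelopes))
    if (length(missing))
      stop("no envelope for tree tip(s): ", paste(missing, collapse = ", "))
    rec <- reconstructEnvelopes(res$tree, res$tip_envelopes)
    res$reconstruction <- rec
    if (!is.null(outdir)) {
      writeBoundsTable(rec$envelopes,
                       file.path(outdir, "ancestral_bounds_table.csv"))
      writeEnvelopes(rec$envelopes,
                     file.path(outdir, "ancestral_envelopes.csv"))
    }
    saveCsv(rec$rates, "bm_rates.csv")
    saveCsv(rec$repairs, "bound_repairs.csv")
    note("reconstructed %d nodes x %d variables; %d interval repair(s)",
         length(rec$envelopes), length(res$variables), nrow(rec$repairs))
  })

  ## -- node projections ---------------------------------------------------
  stage("project", {
    minPP <- if (is.null(config$min_pp)) 0.95 else config$min_pp
    nodes <- supportedNodes(res$tree, minPP)
    note("%d node(s) above pp %.2f selected for projection",
         length(nodes), minPP)
    res$supported_nodes <- nodes
    res$node_projections <- projectNodes(
      nodes, res$reconstruction$envelopes, res$scenarios, res$present,
      ages = nodeAges(res$tree), outdir = outdir)
    for (p in res$node_projections)
      note("node %s (%.2f Ma) -> scenario '%s' and present",
           p$node, p$age, p$scenario)
  })

  ## -- overlap ------------------------------------------------------------
  stage("overlap", {
    surfs <- lapply(res$tip_envelopes, projectEnvelope,
                    scenario = res$present)
    res$tip_surfaces <- surfs
    res$overlap <- overlapMatrix(surfs)
    res$overlap_summary <- overlapSummary(res$overlap, tree = res$tree)
    if (!is.null(outdir)) {
      utils::write.csv(res$overlap$D, file.path(outdir, "overlap_D.csv"))
      utils::write.csv(res$overlap$I, file.path(outdir, "overlap_I.csv"))
    }
    saveCsv(res$overlap_summary, "overlap_summary.csv")
    allRows <- res$overlap_summary[res$overlap_summary$set == "all", ]
    note("niche overlap: mean D %.3f, mean I %.3f over %d pairs",
         allRows$mean[allRows$statistic == "D"],
         allRows$mean[allRows$statistic == "I"], allRows$n_pairs[1L])
  })

  ## -- age-range correlation ---------------------------------------------
  stage("arc", {
    arcCfg <- config$arc
    res$arc <- ageRangeCorrelation(
      res$overlap, res$tree,
      statistic = if (is.null(arcCfg$statistic)) "D" else arcCfg$statistic,
      nPermutations = if (is.null(arcCfg$n_permutations)) 1000L else
        as.integer(arcCfg$n_permutations),
      seed = subSeed(seed, 9000L))
    saveCsv(as.data.frame(res$arc), "arc.csv")
    note("age-range correlation: slope %.4g, adjusted r2 %.3f, permutation p %.3f",
         res$arc$slope, res$arc$adjusted_r2, res$arc$p_value)
  })

  ## -- manifest -----------------------------------------------------------
  stage("manifest", {
    res$manifest <- list(
      package = "paleoniche",
      version = as.character(utils::packageVersion("paleoniche")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = seed,
      config_hash = configHash(config),
      variables = res$variables,
      n_species = length(res$occ),
      n_supported_nodes = length(res$supported_nodes)
    )
    if (!is.null(outdir))
      jsonlite::write_json(res$manifest,
                           file.path(outdir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
  })
  res$log <- logLines
  res
}

#' Project selected nodes into their assigned and the present scenario
#'
#' For every supported node: pick the scenario closest in age to the node
#' ([assignScenario()]), project the node's ancestral envelope into it and
#' into the present-day scenario, and (when \code{outdir} is given) write
#' all four rasters (two suitability surfaces, two classified maps).
#'
#' @param nodes integer node ids.
#' @param envelopes named list of ancestral [EnvelopeModel-class] (names =
#'   node ids).
#' @param scenarios list of candidate [ClimateScenario-class].
#' @param present the present-day [ClimateScenario-class].
#' @param ages node ages indexed by node id (see [nodeAges()]).
#' @param outdir optional artifact directory.
#' @return list per node: \code{node}, \code{age}, \code{scenario} (name),
#'   \code{assigned} and \code{present} ([SuitabilitySurface-class]).
#' @export
projectNodes <- function(nodes, envelopes, scenarios, present, ages,
                         outdir = NULL) {
  lapply(nodes, function(nd) {
    env <- envelopes[[as.character(nd)]]
    if (is.null(env)) stop("no ancestral envelope for node ", nd)
    sc <- assignScenario(ages[nd], scenarios)
    sAssigned <- projectEnvelope(env, sc)
    sPresent <- projectEnvelope(env, present)
    if (!is.null(outdir)) {
      base <- file.path(outdir, sprintf("node_%s", nd))
      writeSurface(sAssigned, paste0(base, "_", sc@name, ".asc"))
      writeSurface(sAssigned, paste0(base, "_", sc@name, "_class.asc"),
                   classified = TRUE)
      writeSurface(sPresent, paste0(base, "_present.asc"))
      writeSurface(sPresent, paste0(base, "_present_class.asc"),
                   classified = TRUE)
    }
    list(node = nd, age = unname(ages[nd]), scenario = sc@name,
         assigned = sAssigned, present = sPresent)
  })
}

## tiny polynomial rolling hash of the deparsed config, for the manifest;
## the output location is not part of the analysis identity
configHash <- function(config) {
  config$output_dir <- NULL
  s <- paste(deparse(config), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
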