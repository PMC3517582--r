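## Correlation-based variable exclusion: of every highly correlated pair,
## drop the variable whose single-variable models discriminate worse (lower
## mean AUC), so the retained set is both weakly correlated and as
## predictive as possible.

#' Pearson correlation matrix of climate variables
#'
#' Pairwise Pearson correlations over the valid rows of a pooled values
#' table (all species' points sampled on one scenario).  Constant columns
#' have undefined correlations; these are set to 0 with a warning so that a
#' constant variable is never flagged as redundant.
#'
#' @param valuesTable output of [sampleValues()] (typically row-bound over
#'   all species).
#' @param variables variable columns to use; default all.
#' @return symmetric correlation matrix with unit diagonal, dimnames the
#'   variable names.
#' @export
correlationMatrix <- function(valuesTable, variables = NULL) {
  vars <- envVarColumns(valuesTable, variables)
  tab <- valuesTable[valuesTable$valid, vars, drop = FALSE]
  if (nrow(tab) < 3L)
    stop("need at least 3 valid points to estimate correlations")
  sds <- vapply(tab, stats::sd, numeric(1))
  r <- suppressWarnings(stats::cor(as.matrix(tab)))
  if (any(sds == 0)) {
    warning("constant variable(s): ",
            paste(vars[sds == 0], collapse = ", "),
            "; correlations set to 0")
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
  }
  diag(r) <- 1
  r
}

#' Exclude correlated variables by mean AUC
#'
#' Implements the exclusion rule behind the four-variable model set: find
#' variable pairs whose correlation exceeds the threshold and drop, from
#' each, the member with the lower mean AUC.  The default order is greedy:
#' the remaining pair with the largest correlation magnitude is resolved
#' first and the search repeats until no pair exceeds the threshold, so the
#' result never contains a pair above the threshold.  \code{order =
#' "single_pass"} instead resolves all offending pairs of the input matrix
#' once, in decreasing correlation order, skipping pairs already broken.
#'
#' By default the magnitude |r| is compared against the threshold: a strong
#' negative correlation is as redundant as a strong positive one.  AUC ties
#' are broken by keeping the variable listed first (\code{tieBreak =
#' "keep_first_listed"}) or raising an error (\code{tieBreak = "error"}).
#'
#' @param corr symmetric correlation matrix with variable dimnames
#'   (see [correlationMatrix()]), or a data frame/matrix coercible to one.
#' @param meanAuc data frame with columns \code{variable}, \code{mean_auc}
#'   covering the same variables (see [meanAucPerVariable()]).
#' @param threshold exclusion threshold on the correlation (default 0.8,
#'   strict inequality).
#' @param useAbsolute compare |r| (default) rather than signed r.
#' @param order \code{"highest_r_first"} (greedy with recomputation,
#'   default) or \code{"single_pass"}.
#' @param tieBreak \code{"keep_first_listed"} (default) or \code{"error"}.
#' @return list with \code{retained} (character vector, input order) and
#'   \code{log} (data frame: one row per exclusion with \code{step},
#'   \code{var_a}, \code{var_b}, \code{r}, \code{dropped}, \code{kept},
#'   \code{auc_dropped}, \code{auc_kept}, \code{reason}).
#' @export
selectVariables <- function(corr, meanAuc, threshold = 0.8,
                            useAbsolute = TRUE,
                            order = c("highest_r_first", "single_pass"),
                            tieBreak = c("keep_first_listed", "error")) {
  order <- match.arg(order)
  tieBreak <- match.arg(tieBreak)
  stopifnot(threshold > 0, threshold <= 1)
  corr <- as.matrix(corr)
  vars <- rownames(corr)
  if (is.null(vars) || !identical(vars, colnames(corr)))
    stop("correlation matrix must have matching row/column variable names")
  if (max(abs(corr), na.rm = TRUE) > 1 + 1e-8 ||
      !isTRUE(all.equal(corr, t(corr), tolerance = 1e-8)))
    stop("correlation matrix must be symmetric with |r| <= 1")
  auc <- meanAuc$mean_auc[match(vars, meanAuc$variable)]
  if (anyNA(auc))
    stop("mean AUC missing for variable(s): ",
         paste(vars[is.na(auc)], collapse = ", "))
  names(auc) <- vars

  strength <- function(m) if (useAbsolute) abs(m) else m
  log <- list()
  alive <- vars
  frozen <- strength(corr)          # for single_pass: pairs of the input
  step <- 0L
  repeat {
    m <- strength(corr[alive, alive, drop = FALSE])
    diag(m) <- -Inf
    if (order == "single_pass" && step > 0L) {
      ## only the original offending pairs are considered, once
      m[] <- -Inf
      mm <- frozen[alive, alive, drop = FALSE]
      diag(mm) <- -Inf
      m[mm > threshold] <- mm[mm > threshold]
    }
    if (!any(m > threshold)) break
    ij <- which(m == max(m), arr.ind = TRUE)[1L, ]
    a <- alive[ij[1L]]; b <- alive[ij[2L]]
    ## orient (a, b) by input order for a stable log
    if (match(a, vars) > match(b, vars)) { tmp <- a; a <- b; b <- tmp }
    if (auc[a] == auc[b]) {
      if (tieBreak == "error")
        stop(sprintf("mean AUC tie between '%s' and '%s' (both %.4g)",
                     a, b, auc[a]))
      dropped <- b; kept <- a
      reason <- "AUC tie; kept first-listed variable"
    } else if (auc[a] < auc[b]) {
      dropped <- a; kept <- b
      reason <- "lower mean AUC"
    } else {
      dropped <- b; kept <- a
      reason <- "lower mean AUC"
    }
    step <- step + 1L
    log[[step]] <- data.frame(
      step = step, var_a = a, var_b = b, r = corr[a, b],
      dropped = dropped, kept = kept,
      auc_dropped = unname(auc[dropped]), auc_kept = unname(auc[kept]),
      reason = reason
    )
    alive <- setdiff(alive, dropped)
    if (length(alive) < 2L) break
  }
  list(retained = vars[vars %in% alive],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(), var_a = character(),
                    var_b = character(), r = numeric(),
                    dropped = character(), kept = character(),
                    auc_dropped = numeric(), auc_kept = numeric(),
                    reason = character()))
}

#' Write a variable-exclusion log
#'
#' One structured-text record per removal, for audit alongside the retained
#' set.
#'
#' @param selection output of [selectVariables()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSelectionLog <- function(selection, path) {
  lines <- c(sprintf("retained: %s",
                     paste(selection$retained, collapse = ", ")))
  if (nrow(selection$log)) {
    lines <- c(lines, apply(selection$log, 1L, function(row)
      sprintf("step %s: |r(%s, %s)| = %s -> dropped %s (mean AUC %s vs %s kept %s): %s",
              row["step"], row["var_a"], row["var_b"], row["r"],
              row["dropped"], row["auc_dropped"], row["auc_kept"],
              row["kept"], row["reason"])))
  }
  writeLines(lines, path)
  invisible(path)
}
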