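## Scenario and occurrence I/O, point-in-cell sampling, occurrence cleaning.

#' Construct a climate scenario from layers
#'
#' @param name scenario label.
#' @param age age in Ma before present (0 = present day).
#' @param layers list of [ClimateLayer-class] objects (co-registered,
#'   unique variable names).
#' @return a [ClimateScenario-class].
#' @export
climateScenario <- function(name, age, layers) {
  new("ClimateScenario", name = name, age = as.numeric(age), layers = layers)
}

#' Construct a climate layer from a matrix
#'
#' @param variable variable name.
#' @param grid numeric matrix, row 1 = northernmost row.
#' @param xll,yll west/south corner in decimal degrees (cell-registered).
#' @param cellsize cell size in degrees.
#' @param nodata no-data sentinel used when writing to disk.
#' @return a [ClimateLayer-class].
#' @export
climateLayer <- function(variable, grid, xll, yll, cellsize, nodata = -9999) {
  new("ClimateLayer", variable = variable, grid = grid, xll = xll, yll = yll,
      cellsize = cellsize, nodata = nodata)
}

#' Construct an occurrence set
#'
#' @param species species name.
#' @param lon,lat coordinate vectors in decimal degrees.
#' @param source free-text provenance.
#' @return an [OccurrenceSet-class].
#' @export
occurrenceSet <- function(species, lon, lat, source = "") {
  new("OccurrenceSet", species = species,
      coords = cbind(lon = as.numeric(lon), lat = as.numeric(lat)),
      source = source)
}

#' Read a climate scenario from a manifest
#'
#' The manifest is a small YAML file naming the scenario, its age in Ma, and
#' one raster file per climate variable:
#' \preformatted{
#' name: present
#' age_ma: 0
#' layers:
#'   Mean_temperature: mean_temperature.asc
#'   Mean_daily_precipitation: mean_daily_precipitation.asc
#' }
#' Raster paths are resolved relative to the manifest's directory.  Layers
#' are returned in manifest order and must be co-registered (same shape,
#' origin and cell size); a mismatch is an error.
#'
#' @param manifestPath path to the manifest file.
#' @return a [ClimateScenario-class].
#' @seealso [writeScenario()]
#' @export
readScenario <- function(manifestPath) {
  if (!file.exists(manifestPath)) stop("no such manifest: ", manifestPath)
  m <- yaml::read_yaml(manifestPath)
  if (is.null(m$layers) || !length(m$layers))
    stop("manifest lists no layers: ", manifestPath)
  vars <- names(m$layers)
  if (is.null(vars) || any(!nzchar(vars)))
    stop("manifest layers must be a variable -> file mapping")
  if (anyDuplicated(vars))
    stop("duplicate variable name in manifest: ",
         paste(unique(vars[duplicated(vars)]), collapse = ", "))
  dir <- dirname(manifestPath)
  layers <- lapply(vars, function(v) {
    f <- file.path(dir, m$layers[[v]])
    readAsciiGrid(f, variable = v)
  })
  climateScenario(name = if (is.null(m$name)) "scenario" else m$name,
                  age = if (is.null(m$age_ma)) 0 else m$age_ma,
                  layers = layers)
}

#' Write a climate scenario (rasters plus manifest)
#'
#' Writes one \code{.asc} file per layer into \code{dir} and a
#' \code{manifest.yml} naming them, the inverse of [readScenario()].
#'
#' @param scenario a [ClimateScenario-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "ClimateScenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  for (l in scenario@layers) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", l@variable), ".asc")
    writeAsciiGrid(l, file.path(dir, fn))
    files[[l@variable]] <- fn
  }
  manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(list(name = scenario@name, age_ma = scenario@age,
                        layers = files), manifest)
  invisible(manifest)
}

## Point -> cell index under the half-open convention:
## columns cover [xll + (c-1)*cs, xll + c*cs) west to east;
## rows cover (ytop - r*cs, ytop - (r-1)*cs] north to south, so the north
## edge belongs to row 1 and every interior horizontal boundary to the cell
## south of it.
pointToCell <- function(lon, lat, xll, yll, cellsize, nr, nc) {
  col <- floor((lon - xll) / cellsize) + 1L
  ytop <- yll + nr * cellsize
  row <- floor((ytop - lat) / cellsize) + 1L
  inside <- col >= 1L & col <= nc & row >= 1L & row <= nr
  list(row = as.integer(row), col = as.integer(col), inside = inside)
}

cellCenters <- function(row, col, xll, yll, cellsize, nr) {
  ytop <- yll + nr * cellsize
  cbind(lon = xll + (col - 0.5) * cellsize,
        lat = ytop - (row - 0.5) * cellsize)
}

#' Sample climate values at points
#'
#' Maps each longitude/latitude point to its containing grid cell (half-open
#' cell intervals; row 1 is the northernmost row) and reads every layer of
#' the scenario at that cell.  Points outside the grid, or whose cell is
#' missing in \emph{any} layer, are flagged invalid rather than dropped;
#' their variable columns are \code{NA}.
#'
#' @param scenario a [ClimateScenario-class] with at least one layer.
#' @param points two-column matrix or data frame of (lon, lat), or an
#'   [OccurrenceSet-class].
#' @return data frame with columns \code{lon}, \code{lat}, \code{row},
#'   \code{col}, \code{valid}, then one column per climate variable.
#' @export
sampleValues <- function(scenario, points) {
  stopifnot(is(scenario, "ClimateScenario"))
  if (!length(scenario@layers)) stop("empty scenario")
  if (is(points, "OccurrenceSet")) points <- occurrenceCoords(points)
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  ref <- scenario@layers[[1L]]
  d <- dim(ref@grid)
  cell <- pointToCell(pts[, 1L], pts[, 2L], ref@xll, ref@yll, ref@cellsize,
                      d[1L], d[2L])
  out <- data.frame(lon = pts[, 1L], lat = pts[, 2L],
                    row = ifelse(cell$inside, cell$row, NA_integer_),
                    col = ifelse(cell$inside, cell$col, NA_integer_),
                    valid = cell$inside)
  idx <- ifelse(cell$inside,
                cell$row + (cell$col - 1L) * d[1L], NA_integer_)
  for (l in scenario@layers) {
    v <- rep(NA_real_, nrow(pts))
    v[cell$inside] <- l@grid[idx[cell$inside]]
    out[[l@variable]] <- v
    out$valid <- out$valid & !is.na(v)
  }
  vars <- variableNames(scenario)
  out[!out$valid, vars] <- NA_real_
  out
}

#' Clean an occurrence set against a scenario
#'
#' Applies the two deterministic cleaning rules: exact coordinate duplicates
#' are collapsed to their first instance, and points that fall outside the
#' scenario grid or on a cell that is missing in any layer (for example,
#' coastal records that land in the ocean) are removed.  The operation is
#' idempotent.
#'
#' @param occ an [OccurrenceSet-class].
#' @param scenario the [ClimateScenario-class] the records will be modelled
#'   against.
#' @return list with elements \code{occurrences} (the cleaned
#'   [OccurrenceSet-class], possibly empty) and \code{report} (counts:
#'   \code{n_input}, \code{n_duplicate}, \code{n_invalid},
#'   \code{n_retained}).
#' @export
cleanOccurrences <- function(occ, scenario) {
  stopifnot(is(occ, "OccurrenceSet"))
  cc <- occ@coords
  dup <- duplicated(cc)
  ccd <- cc[!dup, , drop = FALSE]
  if (nrow(ccd)) {
    sv <- sampleValues(scenario, ccd)
    keep <- sv$valid
  } else {
    keep <- logical(0)
  }
  cleaned <- new("OccurrenceSet", species = occ@species,
                 coords = ccd[keep, , drop = FALSE], source = occ@source)
  list(
    occurrences = cleaned,
    report = data.frame(
      species = occ@species,
      n_input = nrow(cc),
      n_duplicate = sum(dup),
      n_invalid = sum(!keep),
      n_retained = sum(keep)
    )
  )
}

#' Read / write occurrence tables
#'
#' Occurrence CSVs have a header \code{species,lon,lat} with an optional
#' \code{source} column and may mix several species; one
#' [OccurrenceSet-class] per species is returned, in order of first
#' appearance.
#'
#' @param path CSV path.
#' @return \code{readOccurrences}: named list of [OccurrenceSet-class].
#' @export
readOccurrences <- function(path) {
  if (!file.exists(path)) stop("no such occurrence file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, lon, lat")
  src <- if ("source" %in% names(df)) df$source else rep("", nrow(df))
  sp <- unique(df$species)
  out <- lapply(sp, function(s) {
    i <- df$species == s
    occurrenceSet(s, df$lon[i], df$lat[i],
                  source = paste(unique(src[i][nzchar(src[i])]),
                                 collapse = "; "))
  })
  stats::setNames(out, sp)
}

#' @rdname readOccurrences
#' @param occList a single [OccurrenceSet-class] or a list of them.
#' @return \code{writeOccurrences}: \code{path}, invisibly.
#' @export
writeOccurrences <- function(occList, path) {
  if (is(occList, "OccurrenceSet")) occList <- list(occList)
  rows <- lapply(occList, function(o)
    data.frame(species = o@species,
               lon = o@coords[, 1L], lat = o@coords[, 2L],
               source = o@source))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
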