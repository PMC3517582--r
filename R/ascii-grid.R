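## ESRI ASCII grid (.asc) input/output.  Cell-registered headers only
## (xllcorner/yllcorner); values are written with the shortest decimal
## representation that reparses to the identical double, so a write/read
## round trip is bit-exact.

#' Read an ESRI ASCII grid
#'
#' Parses a cell-registered ESRI ASCII raster (header keys \code{ncols},
#' \code{nrows}, \code{xllcorner}, \code{yllcorner}, \code{cellsize},
#' \code{NODATA_value}) into a [ClimateLayer-class].  Cells equal to the
#' no-data sentinel become \code{NA}.
#'
#' @param path path to the \code{.asc} file.
#' @param variable variable name to attach; defaults to the file base name.
#' @return a [ClimateLayer-class].
#' @export
readAsciiGrid <- function(path, variable = NULL) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- list()
  n_hdr <- 0L
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("unexpected end of file in header: ", path)
    parts <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    key <- tolower(parts[1L])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2L])
      n_hdr <- n_hdr + 1L
    } else {
      seek(con, pos)
      break
    }
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("missing header keys in ", path, ": ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(con, what = double(), n = nc * nr, quiet = TRUE)
  if (length(vals) != nc * nr)
    stop(sprintf("expected %d cells, found %d in %s", nc * nr,
                 length(vals), path))
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == nodata] <- NA_real_
  if (is.null(variable))
    variable <- sub("\\.[^.]*$", "", basename(path))
  new("ClimateLayer", variable = variable, grid = g,
      xll = hdr$xllcorner, yll = hdr$yllcorner,
      cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [readAsciiGrid()].  \code{NA} cells are written as the layer's
#' no-data sentinel; finite values are written with enough digits that
#' reading the file back reproduces them exactly.
#'
#' @param layer a [ClimateLayer-class] (or a [SuitabilitySurface-class] via
#'   [writeSurface()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  stopifnot(is(layer, "ClimateLayer"))
  g <- layer@grid
  writeGridFile(g, path, layer@xll, layer@yll, layer@cellsize, layer@nodata)
}

## shortest decimal string that reparses to the identical double
formatExact <- function(x) {
  out <- sprintf("%.15g", x)
  bad <- which(!is.na(x) & suppressWarnings(as.numeric(out)) != x)
  if (length(bad)) {
    out[bad] <- sprintf("%.16g", x[bad])
    bad2 <- bad[suppressWarnings(as.numeric(out[bad])) != x[bad]]
    out[bad2] <- sprintf("%.17g", x[bad2])
  }
  out
}

writeGridFile <- function(g, path, xll, yll, cellsize, nodata = -9999) {
  nr <- nrow(g); nc <- ncol(g)
  vals <- t(g)                         # row-major on disk
  txt <- formatExact(as.vector(vals))
  txt[is.na(as.vector(vals))] <- formatExact(nodata)
  rows <- vapply(seq_len(nr), function(r)
    paste(txt[((r - 1L) * nc + 1L):(r * nc)], collapse = " "), character(1))
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", formatExact(xll)),
    paste("yllcorner", formatExact(yll)),
    paste("cellsize", formatExact(cellsize)),
    paste("NODATA_value", formatExact(nodata))
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a suitability surface or classified map as an ASCII grid
#'
#' Suitability values are written as-is; a classified map (see
#' [classifySurface()]) is written with integer codes 0 (below), 1
#' (all-but-one variable), 2 (all variables).
#'
#' @param surface a [SuitabilitySurface-class].
#' @param path output path.
#' @param classified write the 0/1/2 classification instead of raw values.
#' @return \code{path}, invisibly.
#' @export
writeSurface <- function(surface, path, classified = FALSE) {
  stopifnot(is(surface, "SuitabilitySurface"))
  g <- if (classified) classifySurface(surface) else surface@grid
  writeGridFile(g, path, surface@xll, surface@yll, surface@cellsize)
}
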