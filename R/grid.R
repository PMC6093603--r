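#' Raster grid container
#'
#' A minimal in-memory raster: a numeric matrix plus the georeferencing
#' header of an ESRI ASCII grid.  Row 1 of the matrix is the northernmost
#' row.  Coordinates refer to cell centres; areas are cell counts times
#' `cell_size^2`.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size edge length of a (square) cell in metres.
#' @param xll,yll x/y coordinate of the lower-left corner, metres.
#' @param nodata sentinel value marking missing cells.
#' @return An object of class `marsh_grid`.
#' @export
marsh_grid <- function(values, cell_size, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata)),
    class = "marsh_grid")
}

#' @export
print.marsh_grid <- function(x, ...) {
  cat(sprintf("<marsh_grid> %d x %d cells, cell size %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  rng <- range(x$values[x$values != x$nodata], finite = TRUE)
  if (all(is.finite(rng)))
    cat(sprintf("  values in [%g, %g], nodata = %g\n", rng[1], rng[2], x$nodata))
  invisible(x)
}

#' @export
dim.marsh_grid <- function(x) dim(x$values)

# Replace the value matrix, keeping the header.
grid_with <- function(grid, values) {
  grid$values <- values
  grid
}

#' Check that two grids share shape, cell size and origin
#'
#' @param a,b `marsh_grid` objects.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
assert_coregistered <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)))
    stop("grids are not co-registered: shapes differ (",
         paste(dim(a$values), collapse = "x"), " vs ",
         paste(dim(b$values), collapse = "x"), ")")
  if (a$cell_size != b$cell_size)
    stop("grids are not co-registered: cell sizes differ")
  if (a$xll != b$xll || a$yll != b$yll)
    stop("grids are not co-registered: origins differ")
  invisible(TRUE)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-key header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`; the nodata key is optional) followed by the
#' row-major body, northernmost row first.
#'
#' @param path file path.
#' @return A [marsh_grid()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("malformed ASCII grid: file too short: ", path)
  hdr <- list()
  body_start <- 1L
  for (i in seq_len(min(7L, length(lines)))) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(toks[2])
      body_start <- i + 1L
    } else break
  }
  for (req in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[req]]))
      stop("malformed ASCII grid header: missing key '", req, "' in ", path)
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrows)
    stop("ASCII grid dimension error: expected ", nrows, " data rows, found ",
         length(body), " in ", path)
  vals <- matrix(NA_real_, nrows, ncols)
  for (i in seq_len(nrows)) {
    row <- as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]])
    if (length(row) != ncols)
      stop("ASCII grid dimension error: row ", i, " has ", length(row),
           " values, expected ", ncols, " in ", path)
    vals[i, ] <- row
  }
  marsh_grid(vals, cell_size = hdr$cellsize, xll = hdr$xllcorner,
             yll = hdr$yllcorner, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]: values are written with 17 significant
#' digits so that doubles round-trip bit-exactly.
#'
#' @param grid a [marsh_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "marsh_grid"))
  v <- grid$values
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", grid$nodata)), con)
  fmt_row <- function(r) paste(sprintf("%.17g", r), collapse = " ")
  writeLines(vapply(seq_len(nrow(v)), function(i) fmt_row(v[i, ]), ""), con)
  invisible(path)
}
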