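# Regular latitude/longitude grids and point extraction.
#
# No reprojection, no interpolation: values are looked up in the containing
# cell only.  Cell ownership follows a single half-open convention so that
# every point on Earth belongs to at most one cell:
#   a cell covers [west, west + size) in longitude and
#   (south, south + size] in latitude, rows running north to south.

#' Define the registration of a regular latitude/longitude grid
#'
#' A `grid_spec` pins down where a raster sits on the globe: the north-west
#' corner of the grid, a square cell size in decimal degrees, the number of
#' rows and columns, and the sentinel used for nodata cells.
#'
#' @param west Longitude of the western edge of the grid (decimal degrees).
#' @param north Latitude of the northern edge of the grid (decimal degrees).
#' @param cellsize Cell size in decimal degrees, equal in both axes.
#' @param nrow,ncol Grid dimensions (row 1 is the northernmost row).
#' @param nodata Sentinel value marking nodata cells. Default `-9999`.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(west = -180, north = 90, cellsize = 2.5, nrow = 72, ncol = 144)
#' @export
grid_spec <- function(west, north, cellsize, nrow, ncol, nodata = -9999) {
  stopifnot(is.numeric(west), is.numeric(north), cellsize > 0,
            nrow >= 1, ncol >= 1)
  east <- west + ncol * cellsize
  south <- north - nrow * cellsize
  if (west < -180 - 1e-9 || east > 180 + 1e-9 ||
      south < -90 - 1e-9 || north > 90 + 1e-9) {
    stop("grid extent [", west, ", ", east, "] x [", south, ", ", north,
         "] falls outside [-180, 180] x [-90, 90]")
  }
  structure(
    list(west = west, north = north, cellsize = cellsize,
         nrow = as.integer(nrow), ncol = as.integer(ncol), nodata = nodata),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$north, x$west))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-9) {
  abs(a$west - b$west) < tol && abs(a$north - b$north) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    a$nrow == b$nrow && a$ncol == b$ncol
}

#' Single-variable environmental raster
#'
#' Wraps a numeric matrix (row 1 = northernmost row) with its [grid_spec()]
#' and a variable name drawn from the package's variable registry (see
#' [env_variables()]).  `NA` entries are treated as nodata.
#'
#' @param spec A [grid_spec()].
#' @param values Numeric matrix of dimension `spec$nrow` x `spec$ncol`.
#' @param variable Variable name; must belong to [env_variables()].
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(spec, values, variable) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$nrow, spec$ncol)))
    stop("values must be a ", spec$nrow, " x ", spec$ncol, " matrix")
  if (!variable %in% env_variables())
    stop("unknown variable '", variable, "'; see env_variables()")
  values[values == spec$nodata] <- NA_real_
  structure(list(spec = spec, values = values, variable = variable),
            class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %s, %d x %d, range [%g, %g]\n", x$variable,
              x$spec$nrow, x$spec$ncol,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Twelve monthly layers of one climate variable
#'
#' Holds January-first monthly layers of mean temperature (deg C), minimum
#' temperature (deg C) or precipitation totals (mm) on a shared grid.
#'
#' @param spec A [grid_spec()].
#' @param layers List of 12 matrices (January first), each `nrow` x `ncol`.
#' @param what One of `"temperature"`, `"tmin"`, `"precipitation"`.
#' @return An object of class `monthly_stack`.
#' @export
monthly_stack <- function(spec, layers,
                          what = c("temperature", "tmin", "precipitation")) {
  what <- match.arg(what)
  stopifnot(inherits(spec, "grid_spec"))
  if (length(layers) != 12L) stop("a monthly stack needs exactly 12 layers")
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(spec$nrow, spec$ncol)))
      stop("each layer must be a ", spec$nrow, " x ", spec$ncol, " matrix")
    m[m == spec$nodata] <- NA_real_
    m
  })
  structure(list(spec = spec, layers = layers, what = what),
            class = "monthly_stack")
}

#' Boolean land mask on a grid
#'
#' @param spec A [grid_spec()].
#' @param land Logical matrix, `TRUE` = land.
#' @return An object of class `land_mask`.
#' @export
land_mask <- function(spec, land) {
  stopifnot(inherits(spec, "grid_spec"))
  land <- as.matrix(land)
  if (!identical(dim(land), c(spec$nrow, spec$ncol)))
    stop("mask must be a ", spec$nrow, " x ", spec$ncol, " matrix")
  storage.mode(land) <- "logical"
  land[is.na(land)] <- FALSE
  structure(list(spec = spec, land = land), class = "land_mask")
}

# Row/column (1-based) of the cell owning each point, NA when off-extent.
# Half-open ownership: [west, west+size) x (south, south+size], so a shared
# vertical edge belongs to the eastern cell and a shared horizontal edge to
# the southern cell (whose northern edge it is).  Row r covers
# y = (north - lat)/size in [r-1, r); column c covers x in [c-1, c).
cell_index <- function(spec, lat, lon) {
  x <- (lon - spec$west) / spec$cellsize
  y <- (spec$north - lat) / spec$cellsize
  col <- floor(x + 1e-12) + 1L
  row <- floor(y + 1e-12) + 1L
  off <- is.na(x) | is.na(y) |
    col < 1L | col > spec$ncol | row < 1L | row > spec$nrow
  row[off] <- NA_integer_
  col[off] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Look up raster values at point locations
#'
#' Each point takes the value of its containing cell under the half-open
#' convention (a cell covers `[west, west+size)` in longitude and
#' `(south, south+size]` in latitude; rows run north to south).  Points
#' off the grid extent, or landing in a nodata cell, yield `NA`.
#'
#' @param grid An [env_grid()].
#' @param lat,lon Numeric vectors of equal length (decimal degrees).
#' @return Numeric vector of cell values (`NA` = off-extent or nodata).
#' @examples
#' gs <- grid_spec(0, 10, 1, 10, 10)
#' g <- env_grid(gs, matrix(7, 10, 10), "MAT")
#' extract_at_points(g, lat = 5.5, lon = 5.5)
#' @export
extract_at_points <- function(grid, lat, lon) {
  stopifnot(inherits(grid, "env_grid"), length(lat) == length(lon))
  idx <- cell_index(grid$spec, lat, lon)
  out <- rep(NA_real_, length(lat))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `nodata_value` header
#' followed by rows north to south).
#'
#' @param path Path to an `.asc` file.
#' @param variable Variable name for the resulting [env_grid()].
#' @return An [env_grid()].
#' @export
read_esri_ascii <- function(path, variable) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("missing header fields in ", path, ": ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$nrows * hdr$ncols)
    stop("expected ", hdr$nrows * hdr$ncols, " cells, got ", length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  spec <- grid_spec(west = hdr$xllcorner,
                    north = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                    cellsize = hdr$cellsize, nrow = hdr$nrows,
                    ncol = hdr$ncols, nodata = nodata)
  env_grid(spec, m, variable)
}

#' Write an ESRI ASCII grid
#'
#' @param grid An [env_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(grid, path) {
  spec <- grid$spec
  vals <- grid$values
  vals[is.na(vals)] <- spec$nodata
  hdr <- c(
    sprintf("ncols %d", spec$ncol),
    sprintf("nrows %d", spec$nrow),
    sprintf("xllcorner %.10g", spec$west),
    sprintf("yllcorner %.10g", spec$north - spec$nrow * spec$cellsize),
    sprintf("cellsize %.10g", spec$cellsize),
    sprintf("nodata_value %.10g", spec$nodata)
  )
  body <- apply(vals, 1, function(r) paste(format(r, trim = TRUE,
                                                  digits = 10),
                                           collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Latitude of each row center (length nrow) and longitude of each column
# center (length ncol); used by the synthetic world.
row_lats <- function(spec) spec$north - (seq_len(spec$nrow) - 0.5) * spec$cellsize
col_lons <- function(spec) spec$west + (seq_len(spec$ncol) - 0.5) * spec$cellsize
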