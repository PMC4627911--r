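#' Regular elevation raster
#'
#' A `dem_grid` is a regular, projected-metre elevation raster stored
#' row-major north-to-south: row 1 is the northernmost row of cells.
#' `origin_easting`/`origin_northing` give the lower-left corner of the
#' grid extent (not a cell centre), as in the ESRI ASCII grid convention.
#'
#' @param values numeric matrix of elevations (metres); row 1 = north.
#' @param cell_size cell edge length in metres, > 0.
#' @param origin_easting,origin_northing lower-left corner coordinates (m).
#' @param nodata_value sentinel used for missing cells (default -9999).
#' @return An object of class `dem_grid`.
#' @export
dem_grid <- function(values, cell_size, origin_easting = 0,
                     origin_northing = 0, nodata_value = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("elevation values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  ok <- values != nodata_value
  if (any(!is.finite(values[ok]))) stop("non-finite elevations outside nodata")
  structure(
    list(values = values, n_rows = nrow(values), n_cols = ncol(values),
         cell_size = as.numeric(cell_size),
         origin_easting = as.numeric(origin_easting),
         origin_northing = as.numeric(origin_northing),
         nodata_value = as.numeric(nodata_value)),
    class = "dem_grid")
}

#' @export
print.dem_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata_value]
  cat(sprintf("dem_grid: %d x %d cells, %g m resolution\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: E [%g, %g], N [%g, %g]\n",
              x$origin_easting, x$origin_easting + x$n_cols * x$cell_size,
              x$origin_northing, x$origin_northing + x$n_rows * x$cell_size))
  if (length(v)) cat(sprintf("  elevation: %.1f .. %.1f m\n", min(v), max(v)))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line ESRI ASCII header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by `nrows` rows of
#' `ncols` elevations, first row northernmost.
#'
#' @param path file path.
#' @return A [dem_grid].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) stop("malformed ESRI ASCII grid: too few lines")
  hdr <- list()
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop("malformed ESRI ASCII grid header at line ", i)
    key <- tolower(parts[1])
    if (key != expected[i])
      stop("malformed ESRI ASCII grid header: expected '", expected[i],
           "', found '", parts[1], "'")
    hdr[[key]] <- as.numeric(parts[2])
    if (is.na(hdr[[key]]))
      stop("malformed ESRI ASCII grid header: non-numeric ", key)
  }
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != hdr$nrows)
    stop("malformed ESRI ASCII grid: expected ", hdr$nrows,
         " data rows, found ", length(body))
  rows <- lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]]))
  nc <- vapply(rows, length, integer(1))
  if (any(nc != hdr$ncols))
    stop("malformed ESRI ASCII grid: ragged row (expected ", hdr$ncols,
         " columns, row ", which(nc != hdr$ncols)[1], " has ",
         nc[nc != hdr$ncols][1], ")")
  values <- do.call(rbind, rows)
  dem_grid(values, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
           hdr$nodata_value)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]; `read_ascii_grid(write_ascii_grid(dem))`
#' reproduces the grid exactly (values are written with full precision).
#'
#' @param dem a [dem_grid].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(dem, path) {
  stopifnot(inherits(dem, "dem_grid"))
  hdr <- c(
    sprintf("ncols %d", dem$n_cols),
    sprintf("nrows %d", dem$n_rows),
    sprintf("xllcorner %.10g", dem$origin_easting),
    sprintf("yllcorner %.10g", dem$origin_northing),
    sprintf("cellsize %.10g", dem$cell_size),
    sprintf("NODATA_value %.10g", dem$nodata_value))
  body <- apply(dem$values, 1, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Cell centre coordinates: column j (1-based) centre easting, row i centre
# northing (row 1 = north).
cell_centre_easting <- function(dem, j) {
  dem$origin_easting + (j - 0.5) * dem$cell_size
}
cell_centre_northing <- function(dem, i) {
  dem$origin_northing + (dem$n_rows - i + 0.5) * dem$cell_size
}

# Nearest-cell indices for projected coordinates. Ties (points equidistant
# between two cell centres, i.e. on a cell boundary) break toward the
# smaller row index, then the smaller column index.
nearest_cell <- function(dem, easting, northing) {
  u <- (easting - dem$origin_easting) / dem$cell_size
  v <- (dem$origin_northing + dem$n_rows * dem$cell_size - northing) /
    dem$cell_size
  outside <- u < 0 | u > dem$n_cols | v < 0 | v > dem$n_rows
  # ceiling(u) maps boundary values (u integer) to the lower-index cell;
  # the domain west/north edge (u or v == 0) has a single candidate.
  col <- pmax(ceiling(u), 1L)
  row <- pmax(ceiling(v), 1L)
  list(row = as.integer(row), col = as.integer(col), outside = outside)
}

#' Extract raster values at points
#'
#' Nearest-cell extraction of a grid (a [dem_grid] or any derived grid of
#' the same shape) at a set of projected points. Points on a cell boundary
#' take the value of the cell with the smaller row, then smaller column,
#' index.
#'
#' @param dem a [dem_grid] defining the geometry.
#' @param points a data.frame with columns `point_id`, `easting`,
#'   `northing` (a point set as produced by [generate_treeline_points()]).
#' @param grid optional matrix with the same shape as `dem$values` whose
#'   values are extracted instead of the elevations (e.g. a slope or
#'   curvature grid).
#' @return `points` with a `value` column appended and a logical
#'   `is_nodata` flag.
#' @export
extract_at_points <- function(dem, points, grid = NULL) {
  stopifnot(inherits(dem, "dem_grid"), is.data.frame(points))
  if (is.null(grid)) grid <- dem$values
  if (!identical(dim(grid), dim(dem$values)))
    stop("grid dimensions do not match the dem")
  idx <- nearest_cell(dem, points$easting, points$northing)
  if (any(idx$outside)) {
    bad <- points$point_id[idx$outside][1]
    stop("point outside grid extent: ", bad)
  }
  val <- grid[cbind(idx$row, idx$col)]
  points$value <- val
  points$is_nodata <- !is.na(val) & val == dem$nodata_value
  points$value[points$is_nodata] <- NA_real_
  points
}

#' Mountain mass index
#'
#' Area (km^2) of the grid above an elevation threshold, a proxy for the
#' thermal mass effect of large mountain massifs on regional treeline
#' limits. The conventional threshold is 1,200 m.
#'
#' @param dem a [dem_grid].
#' @param threshold elevation threshold in metres (default 1200).
#' @return Area above the threshold in km^2.
#' @export
mountain_mass_index <- function(dem, threshold = 1200) {
  stopifnot(inherits(dem, "dem_grid"))
  v <- dem$values
  n_above <- sum(v != dem$nodata_value & v > threshold)
  n_above * dem$cell_size^2 / 1e6
}
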