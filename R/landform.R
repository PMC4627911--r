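#' Slope gradient (percent) by the Horn operator
#'
#' Rate of maximum change in elevation within each 3 x 3 neighbourhood.
#' With window
#' \preformatted{ a b c
#'  d e f
#'  g h i }
#' (row above = north) and cell size L,
#' `dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8L)`,
#' `dz/dy = ((g + 2h + i) - (a + 2b + c)) / (8L)`, and
#' `slope% = 100 * sqrt((dz/dx)^2 + (dz/dy)^2)`.
#' Border cells and any window containing a nodata cell yield nodata.
#'
#' @param dem a [dem_grid], at least 3 x 3.
#' @return Matrix of slope percentages with the grid's shape; nodata cells
#'   carry the dem's `nodata_value`.
#' @export
slope_percent <- function(dem) {
  win <- window_stacks(dem)
  L <- dem$cell_size
  dzdx <- ((win$c + 2 * win$f + win$i) - (win$a + 2 * win$d + win$g)) / (8 * L)
  dzdy <- ((win$g + 2 * win$h + win$i) - (win$a + 2 * win$b + win$c)) / (8 * L)
  out <- 100 * sqrt(dzdx^2 + dzdy^2)
  fill_interior(dem, out, win$any_nodata)
}

#' Surface curvature (Zevenbergen-Thorne)
#'
#' General curvature from a polynomial fit to the 3 x 3 elevation window,
#' positive for convex and negative for concave landforms. With north (Z2),
#' west (Z4), centre (Z5), east (Z6) and south (Z8) neighbours and cell
#' size L:
#' `D = ((Z4 + Z6)/2 - Z5) / L^2`, `E = ((Z2 + Z8)/2 - Z5) / L^2`,
#' `curvature = -2 (D + E) * 100`.
#' Units are 1/(100 m), the scale used by standard GIS curvature tools.
#' Border cells and windows containing nodata yield nodata.
#'
#' @inheritParams slope_percent
#' @return Matrix of curvatures with the grid's shape.
#' @export
curvature <- function(dem) {
  win <- window_stacks(dem)
  L <- dem$cell_size
  D <- ((win$d + win$f) / 2 - win$e) / L^2
  E <- ((win$b + win$h) / 2 - win$e) / L^2
  out <- -2 * (D + E) * 100
  fill_interior(dem, out, win$any_nodata)
}

# Shifted copies of the interior 3x3 window: letters follow the
#   a b c
#   d e f
#   g h i
# layout with row 1 (a b c) the northern row. Returns matrices of the
# interior shape plus a nodata mask.
window_stacks <- function(dem) {
  stopifnot(inherits(dem, "dem_grid"))
  if (dem$n_rows < 3 || dem$n_cols < 3)
    stop("dem must be at least 3 x 3 for neighbourhood operators")
  v <- dem$values
  v[v == dem$nodata_value] <- NA_real_
  nr <- dem$n_rows; nc <- dem$n_cols
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  sh <- function(dr, dc) v[ri + dr, ci + dc, drop = FALSE]
  w <- list(a = sh(-1, -1), b = sh(-1, 0), c = sh(-1, 1),
            d = sh(0, -1), e = sh(0, 0), f = sh(0, 1),
            g = sh(1, -1), h = sh(1, 0), i = sh(1, 1))
  w$any_nodata <- Reduce(`|`, lapply(w, is.na))
  w
}

fill_interior <- function(dem, interior, bad) {
  interior[bad] <- dem$nodata_value
  out <- matrix(dem$nodata_value, dem$n_rows, dem$n_cols)
  out[2:(dem$n_rows - 1), 2:(dem$n_cols - 1)] <- interior
  out
}

#' Elevation deviation from the site maximum
#'
#' For every treeline point, the difference between the maximum observed
#' treeline elevation in its study area and the point's elevation. The
#' highest point in each site anchors the local climatic treeline, so
#' deviations are >= 0 and at least one point per site has deviation 0.
#'
#' @param points data.frame with columns `site_id`, `point_id` and
#'   `elevation` (m).
#' @return `points` with `site_max_elevation` and `elevation_deviation`
#'   columns appended.
#' @export
elevation_deviation <- function(points) {
  stopifnot(is.data.frame(points))
  need <- c("site_id", "point_id", "elevation")
  miss <- setdiff(need, names(points))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(points) == 0) stop("no points to group by site")
  if (any(!is.finite(points$elevation))) stop("non-finite elevations")
  site_max <- tapply(points$elevation, points$site_id, max)
  points$site_max_elevation <- as.numeric(site_max[as.character(points$site_id)])
  points$elevation_deviation <- points$site_max_elevation - points$elevation
  points
}
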