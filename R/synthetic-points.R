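#' Specification of a known deviation-generating effect
#'
#' Defines the true data-generating process for synthetic treeline
#' elevation deviations so downstream estimators can be checked by
#' parameter recovery: deviation = intercept + beta_curvature * curvature
#' + beta_slope * slope + sum(beta_index * named feature) + step terms +
#' Gaussian noise.
#'
#' @param intercept baseline deviation (m).
#' @param beta_curvature effect per curvature unit (m).
#' @param beta_slope effect per percent slope (m).
#' @param beta_index named numeric vector: effect per unit of additional
#'   named features (m); names must match columns of the covariate table
#'   supplied at generation time.
#' @param threshold_terms optional list of `list(variable, threshold,
#'   step)` triples adding `step` metres where `variable > threshold`.
#' @param noise_sd Gaussian noise on the deviation (m, >= 0).
#' @param seed integer seed.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(intercept = 150, beta_curvature = 0, beta_slope = 0,
                        beta_index = numeric(0), threshold_terms = list(),
                        noise_sd = 20, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(beta_index) && is.null(names(beta_index)))
    stop("beta_index must be a named vector")
  for (tt in threshold_terms)
    if (length(tt) != 3) stop("threshold_terms entries are (variable, threshold, step)")
  structure(list(intercept = intercept, beta_curvature = beta_curvature,
                 beta_slope = beta_slope, beta_index = beta_index,
                 threshold_terms = threshold_terms, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

#' Generate treeline points with known true deviations
#'
#' Samples `n_points` interior cells of the DEM (interior so that slope
#' and curvature are defined), computes the true deviation from the effect
#' specification using the cell's landform features (and optional
#' per-point covariates), and realises point elevations as the site
#' maximum elevation minus the deviation, floored at the DEM minimum.
#' The true deviation and the generating coefficients are attached as
#' attributes for recovery tests.
#'
#' @param dem a [dem_grid].
#' @param effect an [effect_spec].
#' @param n_points number of points (>= 2).
#' @param site_id site label.
#' @param covariates optional data.frame of `n_points` rows providing the
#'   features named in `beta_index` / `threshold_terms`.
#' @return data.frame with `point_id`, `site_id`, `easting`, `northing`,
#'   `elevation`, `curvature`, `slope_percent`, `true_deviation` (and any
#'   covariate columns); attribute `effect` carries the generating spec.
#' @export
generate_treeline_points <- function(dem, effect, n_points, site_id = "S1",
                                     covariates = NULL) {
  stopifnot(inherits(dem, "dem_grid"), inherits(effect, "effect_spec"))
  if (n_points < 2) stop("n_points must be >= 2")
  if (dem$n_rows < 3 || dem$n_cols < 3)
    stop("empty interior: dem must be at least 3 x 3")
  if (!is.null(covariates) && nrow(covariates) != n_points)
    stop("covariates must have one row per point")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(effect$seed)

  rows <- sample(2:(dem$n_rows - 1), n_points, replace = TRUE)
  cols <- sample(2:(dem$n_cols - 1), n_points, replace = TRUE)
  curv <- curvature(dem)[cbind(rows, cols)]
  slp <- slope_percent(dem)[cbind(rows, cols)]

  dev_true <- effect$intercept + effect$beta_curvature * curv +
    effect$beta_slope * slp
  for (nm in names(effect$beta_index)) {
    if (is.null(covariates) || !nm %in% names(covariates))
      stop("beta_index feature not in covariates: ", nm)
    dev_true <- dev_true + effect$beta_index[[nm]] * covariates[[nm]]
  }
  for (tt in effect$threshold_terms) {
    nm <- tt[[1]]
    if (is.null(covariates) || !nm %in% names(covariates))
      stop("threshold feature not in covariates: ", nm)
    dev_true <- dev_true + tt[[3]] * (covariates[[nm]] > tt[[2]])
  }
  dev_true <- dev_true + stats::rnorm(n_points, 0, effect$noise_sd)

  site_max <- max(dem$values[dem$values != dem$nodata_value])
  dem_min <- min(dem$values[dem$values != dem$nodata_value])
  elev <- pmax(site_max - dev_true, dem_min)

  out <- data.frame(
    point_id = sprintf("%s_p%04d", site_id, seq_len(n_points)),
    site_id = site_id,
    easting = cell_centre_easting(dem, cols),
    northing = cell_centre_northing(dem, rows),
    elevation = elev, curvature = curv, slope_percent = slp,
    true_deviation = dev_true, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  attr(out, "effect") <- effect
  out
}

#' Generate synthetic regional covariates
#'
#' One row per site of plausible regional-scale drivers: growing season
#' temperature (uniform 9-14 deg C), annual precipitation (uniform
#' 1,000-9,000 mm), earthquake intensity (uniform 0-1, proportion of g)
#' and a non-negative erosion index (uniform 0-10). Deterministic given
#' the seed.
#'
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @return data.frame with columns `site_id`, `growing_season_temp`,
#'   `annual_precipitation`, `earthquake_intensity`, `erosion_index`.
#' @export
generate_regional_covariates <- function(n_sites, seed = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  data.frame(
    site_id = sprintf("S%02d", seq_len(n_sites)),
    growing_season_temp = stats::runif(n_sites, 9, 14),
    annual_precipitation = stats::runif(n_sites, 1000, 9000),
    earthquake_intensity = stats::runif(n_sites, 0, 1),
    erosion_index = stats::runif(n_sites, 0, 10),
    stringsAsFactors = FALSE)
}
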