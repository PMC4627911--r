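#' Specification for a synthetic mountain terrain
#'
#' Parameters of the sinusoidal ridge-and-valley surface used to emulate a
#' 7 x 7 km study-area DEM at 200 m resolution. The surface is
#' `base_elevation + (relief_amplitude/4) * (sin(2*pi*x/w) + sin(2*pi*y/w))`
#' plus independent Gaussian cell noise, so the deterministic relief range
#' is `relief_amplitude` when the grid samples the sinusoid peaks.
#'
#' @param n_rows,n_cols grid dimensions in cells (>= 3).
#' @param cell_size cell edge in metres (default 200).
#' @param base_elevation mean elevation of the surface (m).
#' @param relief_amplitude peak-to-trough range of the deterministic
#'   relief (m, >= 0).
#' @param ridge_wavelength wavelength of the ridges/valleys (m).
#' @param noise_sd standard deviation of per-cell Gaussian noise (m, >= 0).
#' @param seed integer seed; identical specs give bit-identical rasters.
#' @return A `terrain_spec` list.
#' @export
terrain_spec <- function(n_rows = 35, n_cols = 35, cell_size = 200,
                         base_elevation = 1100, relief_amplitude = 400,
                         ridge_wavelength = 2000, noise_sd = 15, seed = 1) {
  if (n_rows < 3 || n_cols < 3) stop("terrain grid must be at least 3 x 3")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (relief_amplitude < 0) stop("relief_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (ridge_wavelength <= 0) stop("ridge_wavelength must be > 0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size, base_elevation = base_elevation,
                 relief_amplitude = relief_amplitude,
                 ridge_wavelength = ridge_wavelength, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "terrain_spec")
}

#' Generate a synthetic DEM
#'
#' @param spec a [terrain_spec].
#' @param origin_easting,origin_northing lower-left corner (m).
#' @return A [dem_grid].
#' @export
generate_dem <- function(spec, origin_easting = 0, origin_northing = 0) {
  stopifnot(inherits(spec, "terrain_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  # cell-centre coordinates; row 1 = north
  x <- (seq_len(spec$n_cols) - 0.5) * spec$cell_size
  y <- (spec$n_rows - seq_len(spec$n_rows) + 0.5) * spec$cell_size
  k <- 2 * pi / spec$ridge_wavelength
  ridge <- outer(sin(k * y), sin(k * x), `+`) # n_rows x n_cols
  z <- spec$base_elevation + (spec$relief_amplitude / 4) * ridge
  z <- z + matrix(stats::rnorm(spec$n_rows * spec$n_cols, 0, spec$noise_sd),
                  spec$n_rows, spec$n_cols)
  dem_grid(z, spec$cell_size, origin_easting, origin_northing)
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
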