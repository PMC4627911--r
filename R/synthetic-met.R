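#' Specification for synthetic hourly mountain meteorology
#'
#' Parameters of the seeded generator that emulates mesoscale-model output:
#' hourly screen-level temperature, 10-m wind speed, relative humidity,
#' incoming shortwave and net radiation, and daily rainfall, for January
#' (austral summer) or July (austral winter).
#'
#' The daylight window is fixed per month for Southern-Hemisphere
#' mid-latitudes: January 06:00-21:00 (15 h), July 08:00-17:00 (9 h).
#'
#' @param month_label `"Jan"` or `"Jul"`.
#' @param n_days days in the simulated month (default 31).
#' @param mean_temp_at_base mean temperature at `base_elevation` (deg C).
#' @param diurnal_range peak-to-trough diurnal temperature range (deg C).
#' @param lapse_rate temperature decrease per metre of elevation
#'   (deg C m^-1, default 0.006).
#' @param mean_wind mean wind speed (m s^-1).
#' @param wind_exposure_gain extra wind per metre of relative elevation in
#'   the surrounding 5 x 5 cell window (m s^-1 m^-1).
#' @param rh_mean mean relative humidity (%, in (0, 100]).
#' @param rh_diurnal_range peak-to-trough diurnal humidity range (%),
#'   anti-phase with temperature.
#' @param solar_peak clear-sky midday shortwave irradiance (W m^-2, > 0).
#' @param cloud_fraction fraction of shortwave removed by cloud, in [0, 1].
#' @param nocturnal_longwave magnitude of outgoing longwave radiation
#'   (W m^-2, > 0); net radiation is shortwave minus this term, so nights
#'   are strictly negative.
#' @param solar_exposure_gain fractional change in shortwave per metre of
#'   relative elevation in the 5 x 5 window (differential irradiation of
#'   exposed versus sheltered terrain).
#' @param longwave_skyview_gain fractional change in outgoing longwave
#'   per metre of relative elevation (convex sites see more sky and lose
#'   more longwave radiation).
#' @param wet_day_prob probability a day is wet, in [0, 1].
#' @param rain_gamma_shape,rain_gamma_scale Gamma parameters of wet-day
#'   rainfall totals (mm).
#' @param temp_noise_sd,rh_noise_sd,wind_noise_sd standard deviations of
#'   the independent Gaussian hour-to-hour noise on each variable.
#' @param seed integer seed; identical specs give bit-identical series.
#' @return A `met_spec` list.
#' @export
met_spec <- function(month_label = c("Jan", "Jul"), n_days = 31,
                     mean_temp_at_base = if (month_label[1] == "Jan") 12 else 2,
                     diurnal_range = 8, lapse_rate = 0.006,
                     mean_wind = 4, wind_exposure_gain = 0.01,
                     rh_mean = 75, rh_diurnal_range = 20,
                     solar_peak = if (month_label[1] == "Jan") 900 else 450,
                     cloud_fraction = 0.4, nocturnal_longwave = 70,
                     wet_day_prob = 0.35, rain_gamma_shape = 1.5,
                     rain_gamma_scale = 8, solar_exposure_gain = 5e-4,
                     longwave_skyview_gain = 1e-3, temp_noise_sd = 0.7,
                     rh_noise_sd = 3, wind_noise_sd = 0.8, seed = 1) {
  month_label <- match.arg(month_label)
  if (cloud_fraction < 0 || cloud_fraction > 1)
    stop("cloud_fraction must be in [0, 1]")
  if (rh_mean <= 0 || rh_mean > 100) stop("rh_mean must be in (0, 100]")
  if (solar_peak <= 0) stop("solar_peak must be > 0")
  if (nocturnal_longwave <= 0) stop("nocturnal_longwave must be > 0")
  if (wet_day_prob < 0 || wet_day_prob > 1)
    stop("wet_day_prob must be in [0, 1]")
  if (n_days < 1) stop("n_days must be >= 1")
  structure(list(month_label = month_label, n_days = as.integer(n_days),
                 mean_temp_at_base = mean_temp_at_base,
                 diurnal_range = diurnal_range, lapse_rate = lapse_rate,
                 mean_wind = mean_wind,
                 wind_exposure_gain = wind_exposure_gain,
                 rh_mean = rh_mean, rh_diurnal_range = rh_diurnal_range,
                 solar_peak = solar_peak, cloud_fraction = cloud_fraction,
                 nocturnal_longwave = nocturnal_longwave,
                 wet_day_prob = wet_day_prob,
                 rain_gamma_shape = rain_gamma_shape,
                 rain_gamma_scale = rain_gamma_scale,
                 solar_exposure_gain = solar_exposure_gain,
                 longwave_skyview_gain = longwave_skyview_gain,
                 temp_noise_sd = temp_noise_sd, rh_noise_sd = rh_noise_sd,
                 wind_noise_sd = wind_noise_sd, seed = as.integer(seed)),
            class = "met_spec")
}

#' Daylight hour window for a month
#'
#' Hours of day (0-23) treated as daylight in the generator: January
#' 06:00-21:00, July 08:00-17:00 (Southern-Hemisphere seasonality).
#'
#' @param month_label `"Jan"` or `"Jul"`.
#' @return Integer vector of daylight hours of day.
#' @export
daylight_hours <- function(month_label) {
  switch(match.arg(month_label, c("Jan", "Jul")),
         Jan = 6:20, Jul = 8:16)
}

#' One location's hourly meteorology for one month
#'
#' @param site_id,point_id labels.
#' @param month_label `"Jan"` or `"Jul"`.
#' @param temp_c,wind_ms,rh_pct,solar_wm2,netrad_wm2 hourly vectors of
#'   equal length `24 * n_days`.
#' @param rain_daily_mm daily rainfall totals, length `n_days`.
#' @return An `hourly_met_series`.
#' @export
hourly_met_series <- function(site_id, point_id, month_label, temp_c,
                              wind_ms, rh_pct, solar_wm2, netrad_wm2,
                              rain_daily_mm) {
  n <- length(temp_c)
  lens <- c(length(wind_ms), length(rh_pct), length(solar_wm2),
            length(netrad_wm2))
  if (any(lens != n)) stop("hourly arrays must have equal length")
  if (n %% 24 != 0) stop("series length must be a multiple of 24")
  if (length(rain_daily_mm) != n / 24)
    stop("rain_daily_mm must have one value per day")
  if (any(rh_pct < 0 | rh_pct > 100)) stop("relative humidity outside [0, 100]")
  if (any(solar_wm2 < 0)) stop("negative solar radiation")
  structure(list(site_id = site_id, point_id = point_id,
                 month_label = month_label, n_days = as.integer(n / 24),
                 hour_of_day = rep(0:23, n / 24),
                 temp_c = as.numeric(temp_c), wind_ms = as.numeric(wind_ms),
                 rh_pct = as.numeric(rh_pct),
                 solar_wm2 = as.numeric(solar_wm2),
                 netrad_wm2 = as.numeric(netrad_wm2),
                 rain_daily_mm = as.numeric(rain_daily_mm)),
            class = "hourly_met_series")
}

#' @export
print.hourly_met_series <- function(x, ...) {
  cat(sprintf("hourly_met_series: site %s point %s, %s, %d days\n",
              x$site_id, x$point_id, x$month_label, x$n_days))
  cat(sprintf("  T %.1f..%.1f C, wind %.1f..%.1f m/s, RH %.0f..%.0f %%\n",
              min(x$temp_c), max(x$temp_c), min(x$wind_ms), max(x$wind_ms),
              min(x$rh_pct), max(x$rh_pct)))
  invisible(x)
}

# Mean elevation of the (border-clipped) 5x5 window around each cell.
local_mean_5x5 <- function(dem) {
  v <- dem$values
  v[v == dem$nodata_value] <- NA_real_
  nr <- nrow(v); nc <- ncol(v)
  s <- matrix(0, nr, nc); n <- matrix(0, nr, nc)
  for (dr in -2:2) for (dc in -2:2) {
    r_src <- pmin(pmax(seq_len(nr) + dr, 1), nr)
    c_src <- pmin(pmax(seq_len(nc) + dc, 1), nc)
    keep_r <- seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr
    keep_c <- seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc
    shifted <- v[r_src, c_src, drop = FALSE]
    shifted[!keep_r, ] <- NA
    shifted[, !keep_c] <- NA
    add <- !is.na(shifted)
    s[add] <- s[add] + shifted[add]
    n <- n + add
  }
  s / pmax(n, 1)
}

#' Generate hourly meteorology at point locations
#'
#' Emulates hourly mesoscale-model output over a DEM. Per location:
#' temperature follows the base-elevation mean minus a fixed lapse with a
#' mid-afternoon diurnal peak plus Gaussian noise; shortwave is a half-sine
#' over the month's daylight window scaled by `1 - cloud_fraction`, zero at
#' night, and modulated per location by terrain exposure
#' (`solar_exposure_gain` x relative elevation); net radiation is
#' shortwave minus the outgoing longwave term, itself scaled by a sky-view
#' factor on exposed terrain, so nights are strictly negative; relative
#' humidity runs anti-phase to temperature and is clipped to [5, 100];
#' wind is the mean plus an exposure term proportional to the location's
#' relative elevation within its 5 x 5 cell window, floored at 0; rain is
#' drawn daily as Bernoulli(`wet_day_prob`) x Gamma.
#'
#' @param dem a [dem_grid].
#' @param spec a [met_spec].
#' @param locations data.frame with `site_id`, `point_id`, `easting`,
#'   `northing` inside the dem extent.
#' @return A list of [hourly_met_series], one per location row.
#' @export
generate_hourly_met <- function(dem, spec, locations) {
  stopifnot(inherits(dem, "dem_grid"), inherits(spec, "met_spec"),
            is.data.frame(locations))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  elev_pts <- extract_at_points(dem, locations)
  if (any(elev_pts$is_nodata))
    stop("location in a nodata cell: ",
         elev_pts$point_id[elev_pts$is_nodata][1])
  rel_elev_grid <- dem$values - local_mean_5x5(dem)
  rel_pts <- extract_at_points(dem, locations, rel_elev_grid)

  n_hours <- 24L * spec$n_days
  hod <- rep(0:23, spec$n_days)
  day_hours <- daylight_hours(spec$month_label)
  is_day <- hod %in% day_hours
  h0 <- min(day_hours); len <- length(day_hours)
  # half-sine over the daylight window, evaluated at mid-hour
  solar_base <- numeric(n_hours)
  solar_base[is_day] <- spec$solar_peak * (1 - spec$cloud_fraction) *
    sin(pi * (hod[is_day] - h0 + 0.5) / len)
  diurnal <- cos(2 * pi * (hod - 15) / 24) # peaks 15:00

  lapply(seq_len(nrow(locations)), function(i) {
    elev <- elev_pts$value[i]
    rel <- rel_pts$value[i]
    solar <- pmax(solar_base * (1 + spec$solar_exposure_gain * rel), 0)
    longwave <- max(spec$nocturnal_longwave *
                      (1 + spec$longwave_skyview_gain * rel), 1)
    t_mean <- spec$mean_temp_at_base -
      spec$lapse_rate * (elev - mean(dem$values[dem$values != dem$nodata_value]))
    temp <- t_mean + (spec$diurnal_range / 2) * diurnal +
      stats::rnorm(n_hours, 0, spec$temp_noise_sd)
    rh <- spec$rh_mean - (spec$rh_diurnal_range / 2) * diurnal +
      stats::rnorm(n_hours, 0, spec$rh_noise_sd)
    rh <- pmin(pmax(rh, 5), 100)
    wind <- spec$mean_wind + spec$wind_exposure_gain * rel +
      stats::rnorm(n_hours, 0, spec$wind_noise_sd)
    wind <- pmax(wind, 0)
    netrad <- solar - longwave
    wet <- stats::rbinom(spec$n_days, 1, spec$wet_day_prob)
    rain <- wet * stats::rgamma(spec$n_days, shape = spec$rain_gamma_shape,
                                scale = spec$rain_gamma_scale)
    hourly_met_series(locations$site_id[i], locations$point_id[i],
                      spec$month_label, temp, wind, rh, solar, netrad, rain)
  })
}

#' Write / read hourly series as long-format CSV
#'
#' One row per location-hour with columns `site_id`, `point_id`, `month`,
#' `timestamp_hour` (1-based hour index in the month), `temp_c`, `wind_ms`,
#' `rh_pct`, `solar_wm2`, `netrad_wm2`, `rain_mm` (the day's rainfall
#' total, repeated on each hour of that day).
#'
#' @param series_list list of [hourly_met_series].
#' @param path CSV path.
#' @return `path` invisibly; `read_hourly_met_csv` returns the series list.
#' @export
write_hourly_met_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(site_id = s$site_id, point_id = s$point_id,
               month = s$month_label,
               timestamp_hour = seq_along(s$temp_c),
               temp_c = s$temp_c, wind_ms = s$wind_ms, rh_pct = s$rh_pct,
               solar_wm2 = s$solar_wm2, netrad_wm2 = s$netrad_wm2,
               rain_mm = rep(s$rain_daily_mm, each = 24),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hourly_met_csv
#' @export
read_hourly_met_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "point_id", "month", "timestamp_hour", "temp_c",
            "wind_ms", "rh_pct", "solar_wm2", "netrad_wm2", "rain_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keys <- unique(df[, c("site_id", "point_id", "month")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$site_id == keys$site_id[i] & df$point_id == keys$point_id[i] &
                df$month == keys$month[i], , drop = FALSE]
    sub <- sub[order(sub$timestamp_hour), , drop = FALSE]
    rain_daily <- sub$rain_mm[seq(1, nrow(sub), by = 24)]
    hourly_met_series(keys$site_id[i], keys$point_id[i], keys$month[i],
                      sub$temp_c, sub$wind_ms, sub$rh_pct, sub$solar_wm2,
                      sub$netrad_wm2, rain_daily)
  })
}
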