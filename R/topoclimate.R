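#' Partition a series into daytime and nighttime hours
#'
#' An hour is daytime when its incoming shortwave exceeds
#' `solar_threshold` (default 1 W m^-2). The stress indices all average
#' over one of these hour sets.
#'
#' @param series an [hourly_met_series].
#' @param solar_threshold W m^-2 above which an hour counts as daytime.
#' @return A `day_night_partition`: logical `daytime` mask plus counts
#'   `n_daytime`, `n_nighttime`, `n_total`.
#' @export
partition_day_night <- function(series, solar_threshold = 1) {
  stopifnot(inherits(series, "hourly_met_series"))
  daytime <- series$solar_wm2 > solar_threshold
  structure(list(daytime = daytime,
                 n_daytime = sum(daytime),
                 n_nighttime = sum(!daytime),
                 n_total = length(daytime)),
            class = "day_night_partition")
}

#' Site-level maxima of temperature and wind speed
#'
#' The maximum hourly temperature and wind speed over every location of a
#' site for one month. These rescale hourly values in the photoinhibition,
#' winter desiccation and frost indices so that cold (or calm) hours carry
#' the most weight.
#'
#' @param series_list non-empty list of [hourly_met_series] from one
#'   site-month.
#' @return A `site_maxima` list: `site_id`, `month_label`, `t_site_max`,
#'   `ws_site_max`.
#' @export
site_maxima <- function(series_list) {
  if (length(series_list) == 0) stop("empty series collection")
  structure(list(
    site_id = series_list[[1]]$site_id,
    month_label = series_list[[1]]$month_label,
    t_site_max = max(vapply(series_list, function(s) max(s$temp_c), 0)),
    ws_site_max = max(vapply(series_list, function(s) max(s$wind_ms), 0))),
    class = "site_maxima")
}

#' Mean photoinhibition index
#'
#' Combined low-temperature / high-irradiance stress: the mean over
#' daytime hours of `(T_site_max - T_hourly) * SolRad_hourly`
#' (units deg C W m^-2). Locations where cold bright hours are frequent
#' score high.
#'
#' @param series an [hourly_met_series].
#' @param maxima a [site_maxima] for the series' site-month.
#' @param partition a [day_night_partition] of the series.
#' @return Index value (>= 0 when `t_site_max` bounds the series).
#' @export
photoinhibition_index <- function(series, maxima, partition) {
  d <- partition$daytime
  if (partition$n_daytime == 0)
    stop("photoinhibition index undefined: no daytime hours")
  sum((maxima$t_site_max - series$temp_c[d]) * series$solar_wm2[d]) /
    partition$n_daytime
}

#' Mean summer desiccation index
#'
#' Daytime mean of `T_hourly * WS_hourly * (100 - RelHum_hourly)`
#' (deg C m s^-1 %): hot, windy, dry daytime hours score high. Computed
#' for January.
#'
#' @inheritParams photoinhibition_index
#' @return Index value.
#' @export
summer_desiccation_index <- function(series, partition) {
  d <- partition$daytime
  if (partition$n_daytime == 0)
    stop("summer desiccation index undefined: no daytime hours")
  sum(series$temp_c[d] * series$wind_ms[d] * (100 - series$rh_pct[d])) /
    partition$n_daytime
}

#' Mean winter desiccation index
#'
#' Frost-drought stress for July: `(T_site_max - T_hourly) * WS_hourly *
#' (100 - RelHum_hourly)` averaged over the month. The divisor is always
#' `N_total`; `hour_set` selects whether the sum runs over all hours
#' (default, following the index's whole-day definition) or daytime hours
#' only (the alternative reading of its summation).
#'
#' @inheritParams photoinhibition_index
#' @param hour_set `"all_hours"` (default) or `"daytime_only"`.
#' @return Index value.
#' @export
winter_desiccation_index <- function(series, maxima, partition,
                                     hour_set = c("all_hours", "daytime_only")) {
  hour_set <- match.arg(hour_set)
  keep <- if (hour_set == "all_hours") rep(TRUE, partition$n_total)
          else partition$daytime
  if (!any(keep)) stop("winter desiccation index undefined: empty hour set")
  sum((maxima$t_site_max - series$temp_c[keep]) * series$wind_ms[keep] *
        (100 - series$rh_pct[keep])) / partition$n_total
}

#' Frost index
#'
#' Radiative-frost potential: nighttime mean of `(T_site_max - T_hourly)
#' * (WS_site_max - WS_hourly) * (-NetRad_hourly)`. Cold, calm, strongly
#' radiating nights (net radiation negative) score high; the index is
#' >= 0 whenever nighttime net radiation is negative throughout.
#'
#' @inheritParams photoinhibition_index
#' @return Index value.
#' @export
frost_index <- function(series, maxima, partition) {
  n <- !partition$daytime
  if (partition$n_nighttime == 0)
    stop("frost index undefined: no nighttime hours")
  sum((maxima$t_site_max - series$temp_c[n]) *
        (maxima$ws_site_max - series$wind_ms[n]) *
        (-series$netrad_wm2[n])) / partition$n_nighttime
}

#' Total daytime insolation
#'
#' Sum of hourly incoming shortwave over daytime hours; with hourly
#' W m^-2 values this is the month's insolation in W h m^-2. The one
#' ameliorative index: high values mark warm, bright locations.
#'
#' @inheritParams photoinhibition_index
#' @return Insolation (>= 0).
#' @export
insolation <- function(series, partition) {
  sum(series$solar_wm2[partition$daytime])
}

#' All five topoclimatic indices for one series
#'
#' Applies the month-appropriate desiccation form: summer (January) uses
#' the daytime product of temperature, wind and dryness; winter (July)
#' uses the whole-day, site-max-rescaled form.
#'
#' @inheritParams photoinhibition_index
#' @param hour_set passed to [winter_desiccation_index()] for July.
#' @return One-row data.frame: `point_id`, `site_id`, `month`,
#'   `photoinhibition`, `desiccation`, `frost`, `insolation`.
#' @export
topoclimate_indices <- function(series, maxima,
                                partition = partition_day_night(series),
                                hour_set = "all_hours") {
  desic <- if (series$month_label == "Jan")
    summer_desiccation_index(series, partition)
  else winter_desiccation_index(series, maxima, partition, hour_set)
  data.frame(point_id = series$point_id, site_id = series$site_id,
             month = series$month_label,
             photoinhibition = photoinhibition_index(series, maxima, partition),
             desiccation = desic,
             frost = frost_index(series, maxima, partition),
             insolation = insolation(series, partition),
             stringsAsFactors = FALSE)
}

#' Monthly meteorological summaries
#'
#' The standard per-month summary row derived from an hourly series:
#' absolute minimum and maximum temperature, wind speed and relative
#' humidity; frost hours (hours below 0 deg C); rain days (days with at
#' least 0.1 mm); total daytime solar radiation; and net outgoing
#' longwave radiation (nighttime mean of `-NetRad`, positive). Ten
#' summaries per month, so January plus July give the full twenty-variable
#' set used in the ordination.
#'
#' @inheritParams photoinhibition_index
#' @param frost_threshold_c temperature below which an hour is a frost
#'   hour (default 0 deg C).
#' @param rain_day_mm daily rainfall at or above which a day is a rain
#'   day (default 0.1 mm).
#' @return One-row data.frame of the ten summaries plus ids; the longwave
#'   summary is `NA` (with a warning) if the series has no nighttime hours.
#' @export
monthly_summaries <- function(series,
                              partition = partition_day_night(series),
                              frost_threshold_c = 0, rain_day_mm = 0.1) {
  stopifnot(inherits(series, "hourly_met_series"))
  night <- !partition$daytime
  if (!any(night)) {
    warning("no nighttime hours: longwave summary undefined")
    lw <- NA_real_
  } else lw <- mean(-series$netrad_wm2[night])
  data.frame(
    point_id = series$point_id, site_id = series$site_id,
    month = series$month_label,
    temp_min = min(series$temp_c), temp_max = max(series$temp_c),
    wind_min = min(series$wind_ms), wind_max = max(series$wind_ms),
    rh_min = min(series$rh_pct), rh_max = max(series$rh_pct),
    frost_hours = sum(series$temp_c < frost_threshold_c),
    rain_days = sum(series$rain_daily_mm >= rain_day_mm),
    total_solar = insolation(series, partition),
    net_longwave = lw, stringsAsFactors = FALSE)
}

#' Index and summary tables for a collection of series
#'
#' Groups series by site and month, computes the site-month maxima, and
#' returns the per-point index table and the per-point monthly summary
#' table.
#'
#' @param series_list list of [hourly_met_series].
#' @param solar_threshold daytime threshold (W m^-2).
#' @param hour_set July desiccation variant, see
#'   [winter_desiccation_index()].
#' @return list with data.frames `indices` and `summaries`.
#' @export
topoclimate_tables <- function(series_list, solar_threshold = 1,
                               hour_set = "all_hours") {
  key <- vapply(series_list, function(s)
    paste(s$site_id, s$month_label, sep = "\r"), "")
  groups <- split(series_list, key)
  idx <- list(); summ <- list()
  for (g in groups) {
    mx <- site_maxima(g)
    for (s in g) {
      p <- partition_day_night(s, solar_threshold)
      idx[[length(idx) + 1]] <- topoclimate_indices(s, mx, p, hour_set)
      summ[[length(summ) + 1]] <- monthly_summaries(s, p)
    }
  }
  list(indices = do.call(rbind, idx), summaries = do.call(rbind, summ))
}
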