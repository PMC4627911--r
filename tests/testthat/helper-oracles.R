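# Independent brute-force oracles and small fixture builders used across
# the test files. All oracles are deliberately naive (explicit per-hour /
# per-cell loops) and share no code with the implementation they check.

# ---- hourly series fixtures -------------------------------------------

# A 24 x n_days series built directly from hourly vectors.
make_series <- function(temp, wind, rh, solar, netrad, rain_daily = NULL,
                        site = "S1", point = "p1", month = "Jan") {
  n_days <- length(temp) / 24
  if (is.null(rain_daily)) rain_daily <- rep(0, n_days)
  hourly_met_series(site, point, month, temp, wind, rh, solar, netrad,
                    rain_daily)
}

# Random but physically sane series: RH in [5,100], solar >= 0 with a
# nocturnal zero block, negative nighttime net radiation.
random_series <- function(n_days = 3, month = "Jan", site = "S1",
                          point = "p1") {
  n <- 24 * n_days
  hod <- rep(0:23, n_days)
  day <- hod %in% 7:18
  solar <- ifelse(day, runif(n, 5, 900), 0)
  make_series(
    temp = runif(n, -10, 25),
    wind = runif(n, 0, 20),
    rh = runif(n, 5, 100),
    solar = solar,
    netrad = solar - runif(n, 30, 120),
    rain_daily = rbinom(n_days, 1, 0.4) * rgamma(n_days, 2, scale = 5),
    site = site, point = point, month = month)
}

manual_maxima <- function(t_max, ws_max, site = "S1", month = "Jan") {
  structure(list(site_id = site, month_label = month,
                 t_site_max = t_max, ws_site_max = ws_max),
            class = "site_maxima")
}

# ---- per-hour loop oracles for the five indices -----------------------

oracle_photoinhibition <- function(s, tmax, day) {
  acc <- 0
  for (i in seq_along(s$temp_c))
    if (day[i]) acc <- acc + (tmax - s$temp_c[i]) * s$solar_wm2[i]
  acc / sum(day)
}

oracle_summer_desiccation <- function(s, day) {
  acc <- 0
  for (i in seq_along(s$temp_c))
    if (day[i]) acc <- acc + s$temp_c[i] * s$wind_ms[i] * (100 - s$rh_pct[i])
  acc / sum(day)
}

oracle_winter_desiccation <- function(s, tmax, day, all_hours = TRUE) {
  acc <- 0
  for (i in seq_along(s$temp_c))
    if (all_hours || day[i])
      acc <- acc + (tmax - s$temp_c[i]) * s$wind_ms[i] * (100 - s$rh_pct[i])
  acc / length(s$temp_c)
}

oracle_frost <- function(s, tmax, wsmax, day) {
  acc <- 0
  for (i in seq_along(s$temp_c))
    if (!day[i]) acc <- acc + (tmax - s$temp_c[i]) *
      (wsmax - s$wind_ms[i]) * (-s$netrad_wm2[i])
  acc / sum(!day)
}

oracle_insolation <- function(s, day) {
  acc <- 0
  for (i in seq_along(s$solar_wm2)) if (day[i]) acc <- acc + s$solar_wm2[i]
  acc
}

# ---- DEM fixtures and per-window landform oracles ---------------------

# dem from a function of cell-centre easting/northing (row 1 = north).
dem_from_fun <- function(n_rows, n_cols, cell, f, origin_e = 0,
                         origin_n = 0) {
  z <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) for (j in seq_len(n_cols)) {
    e <- origin_e + (j - 0.5) * cell
    n <- origin_n + (n_rows - i + 0.5) * cell
    z[i, j] <- f(e, n)
  }
  dem_grid(z, cell, origin_e, origin_n)
}

# Naive per-window Horn slope and Zevenbergen-Thorne curvature.
oracle_slope_cell <- function(v, i, j, L) {
  a <- v[i - 1, j - 1]; b <- v[i - 1, j]; c <- v[i - 1, j + 1]
  d <- v[i, j - 1];                        f <- v[i, j + 1]
  g <- v[i + 1, j - 1]; h <- v[i + 1, j]; k <- v[i + 1, j + 1]
  dzdx <- ((c + 2 * f + k) - (a + 2 * d + g)) / (8 * L)
  dzdy <- ((g + 2 * h + k) - (a + 2 * b + c)) / (8 * L)
  100 * sqrt(dzdx^2 + dzdy^2)
}

oracle_curv_cell <- function(v, i, j, L) {
  z2 <- v[i - 1, j]; z4 <- v[i, j - 1]; z5 <- v[i, j]
  z6 <- v[i, j + 1]; z8 <- v[i + 1, j]
  D <- ((z4 + z6) / 2 - z5) / L^2
  E <- ((z2 + z8) / 2 - z5) / L^2
  -2 * (D + E) * 100
}

# ---- feature-table fixture for the modeling module --------------------

# n rows x the 17 standard explanatory variables, all independent noise,
# plus a response column built by `f(table)` + Gaussian noise.
synthetic_feature_table <- function(n, f = function(tab) rep(0, n),
                                    noise_sd = 1, seed = 1) {
  set.seed(seed)
  tab <- data.frame(
    curvature = rnorm(n, 0, 0.3),
    slope_percent = runif(n, 0, 150),
    photoinhibition_jan = rgamma(n, 2, scale = 1500),
    photoinhibition_jul = rgamma(n, 2, scale = 800),
    desiccation_jan = rnorm(n, 4000, 1200),
    desiccation_jul = rgamma(n, 2, scale = 2500),
    frost_jan = rgamma(n, 2, scale = 4000),
    frost_jul = rgamma(n, 2, scale = 9000),
    insolation_jan = rnorm(n, 160000, 25000),
    insolation_jul = rnorm(n, 45000, 9000),
    growing_season_temp = runif(n, 9, 14),
    annual_precipitation = runif(n, 1000, 9000),
    mountain_mass_index = runif(n, 0, 49),
    earthquake_intensity = runif(n, 0, 1),
    erosion_index = runif(n, 0, 10),
    winter_temp_min = runif(n, -12, -2),
    winter_temp_max = runif(n, 2, 10))
  tab$elevation_deviation <- f(tab) + rnorm(n, 0, noise_sd)
  tab
}
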