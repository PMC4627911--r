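# The five topoclimatic indices and the monthly summary variables:
# direct evaluations, zero cases, per-hour loop oracle agreement, and
# scale/monotonicity properties.

test_that("day/night partition follows the solar threshold", {
  s <- make_series(rep(5, 48), rep(1, 48), rep(50, 48),
                   solar = rep(0, 48), netrad = rep(-60, 48))
  p <- partition_day_night(s)
  expect_equal(p$n_daytime, 0)
  expect_equal(p$n_nighttime, 48)

  s2 <- make_series(rep(5, 24), rep(1, 24), rep(50, 24),
                    solar = rep(10, 24), netrad = rep(-50, 24))
  expect_equal(partition_day_night(s2)$n_nighttime, 0)

  # synthetic January: 15 daylight hours x 31 days
  dem <- dem_grid(matrix(1000, 5, 5), 200)
  pts <- data.frame(point_id = "p1", site_id = "S1", easting = 500,
                    northing = 500)
  jan <- generate_hourly_met(dem, met_spec("Jan", seed = 1), pts)[[1]]
  expect_equal(partition_day_night(jan)$n_daytime, 465)
})

test_that("site maxima bound every hour of every member series", {
  s1 <- make_series(rep(10, 24), rep(3, 24), rep(60, 24),
                    rep(0, 24), rep(-50, 24))
  expect_equal(site_maxima(list(s1))$t_site_max, 10)
  s2 <- make_series(c(rep(12, 23), 15), c(rep(3, 23), 8), rep(60, 24),
                    rep(0, 24), rep(-50, 24), point = "p2")
  mx <- site_maxima(list(s1, s2))
  expect_equal(mx$t_site_max, 15)
  expect_equal(mx$ws_site_max, 8)
  set.seed(4)
  rs <- replicate(3, random_series(), simplify = FALSE)
  mx <- site_maxima(rs)
  expect_equal(mx$t_site_max, max(sapply(rs, function(s) max(s$temp_c))))
  expect_error(site_maxima(list()), "empty")
})

test_that("photoinhibition index evaluates its defining sum", {
  # 2 daytime hours: T_site_max 20, T = 10, 15, solar = 500, 800
  temp <- rep(0, 24); solar <- rep(0, 24)
  temp[10] <- 10; temp[11] <- 15
  solar[10] <- 500; solar[11] <- 800
  s <- make_series(temp, rep(2, 24), rep(60, 24), solar, solar - 70)
  p <- partition_day_night(s)
  expect_equal(p$n_daytime, 2)
  mx <- manual_maxima(20, 10)
  expect_equal(photoinhibition_index(s, mx, p), (10 * 500 + 5 * 800) / 2)
  # T at the site max zeroes the index
  s0 <- make_series(rep(20, 24), rep(2, 24), rep(60, 24), solar, solar - 70)
  expect_equal(photoinhibition_index(s0, mx, partition_day_night(s0)), 0)
  # linear in solar radiation
  s2 <- make_series(temp, rep(2, 24), rep(60, 24), 2 * solar, solar - 70)
  expect_equal(photoinhibition_index(s2, mx, partition_day_night(s2)),
               2 * 4500)
  # no daytime hours is an error, not a silent zero
  night <- make_series(rep(1, 24), rep(1, 24), rep(60, 24), rep(0, 24),
                       rep(-60, 24))
  expect_error(photoinhibition_index(night, mx, partition_day_night(night)),
               "undefined|no daytime")
})

test_that("summer desiccation index evaluates its defining sum", {
  # single daytime hour: T 20, WS 5, RH 40
  temp <- rep(0, 24); wind <- rep(0, 24); rh <- rep(100, 24)
  solar <- rep(0, 24)
  temp[12] <- 20; wind[12] <- 5; rh[12] <- 40; solar[12] <- 600
  s <- make_series(temp, wind, rh, solar, solar - 70)
  p <- partition_day_night(s)
  expect_equal(summer_desiccation_index(s, p), 20 * 5 * 60)
  # saturated humidity or calm wind zero the index
  s_rh <- make_series(temp, wind, rep(100, 24), solar, solar - 70)
  expect_equal(summer_desiccation_index(s_rh, partition_day_night(s_rh)), 0)
  wind0 <- rep(0, 24)
  s_w <- make_series(temp, wind0, rh, solar, solar - 70)
  expect_equal(summer_desiccation_index(s_w, partition_day_night(s_w)), 0)
})

test_that("winter desiccation divides by total hours in both variants", {
  # 12 daytime hours (T 0, WS 10, RH 70) and 12 nighttime hours
  # (T -5, WS 10, RH 80); T_site_max = 5
  day <- rep(c(FALSE, TRUE), each = 12)
  temp <- ifelse(day, 0, -5)
  wind <- rep(10, 24)
  rh <- ifelse(day, 70, 80)
  solar <- ifelse(day, 400, 0)
  s <- make_series(temp, wind, rh, solar, solar - 70)
  p <- partition_day_night(s)
  mx <- manual_maxima(5, 10)
  # all-hours sum: 12*(5*10*30) + 12*(10*10*20), over N_total = 24
  expect_equal(winter_desiccation_index(s, mx, p), 1750)
  expect_equal(winter_desiccation_index(s, mx, p, "daytime_only"), 750)
  # T at site max zeroes the index
  s0 <- make_series(rep(5, 24), wind, rh, solar, solar - 70)
  expect_equal(winter_desiccation_index(s0, mx, partition_day_night(s0)), 0)
})

test_that("frost index evaluates its defining sum and stays non-negative", {
  # one nighttime hour: T -2, WS 2, NetRad -80; T_site_max 15, WS max 12
  temp <- rep(15, 24); wind <- rep(12, 24); solar <- rep(500, 24)
  netrad <- solar - 70
  temp[3] <- -2; wind[3] <- 2; solar[3] <- 0; netrad[3] <- -80
  s <- make_series(temp, wind, rep(60, 24), solar, netrad)
  p <- partition_day_night(s)
  expect_equal(p$n_nighttime, 1)
  mx <- manual_maxima(15, 12)
  expect_equal(frost_index(s, mx, p), 17 * 10 * 80)
  # wind at the site max zeroes the index
  s_w <- make_series(temp, rep(12, 24), rep(60, 24), solar, netrad)
  expect_equal(frost_index(s_w, mx, partition_day_night(s_w)), 0)
  # negative nighttime net radiation keeps the index non-negative
  set.seed(31)
  for (i in 1:20) {
    rs <- random_series()
    prt <- partition_day_night(rs)
    rmx <- site_maxima(list(rs))
    expect_gte(frost_index(rs, rmx, prt), 0)
    expect_gte(photoinhibition_index(rs, rmx, prt), 0)
  }
})

test_that("insolation sums daytime shortwave and ignores the night", {
  solar <- rep(0, 24)
  solar[10:12] <- c(100, 500, 300)
  s <- make_series(rep(5, 24), rep(1, 24), rep(50, 24), solar, solar - 70)
  expect_equal(insolation(s, partition_day_night(s)), 900)
  zero <- make_series(rep(5, 24), rep(1, 24), rep(50, 24), rep(0, 24),
                      rep(-70, 24))
  expect_equal(insolation(zero, partition_day_night(zero)), 0)
  # nighttime values of other variables are irrelevant
  s2 <- make_series(rnorm(24, 5), runif(24, 0, 9), rep(50, 24), solar,
                    solar - 120)
  expect_equal(insolation(s2, partition_day_night(s2)), 900)
})

test_that("every index matches its naive per-hour loop oracle", {
  set.seed(77)
  for (i in 1:25) {
    s <- random_series(n_days = 2)
    p <- partition_day_night(s)
    mx <- site_maxima(list(s, random_series(n_days = 2, point = "p2")))
    day <- p$daytime
    expect_equal(photoinhibition_index(s, mx, p),
                 oracle_photoinhibition(s, mx$t_site_max, day),
                 tolerance = 1e-10)
    expect_equal(summer_desiccation_index(s, p),
                 oracle_summer_desiccation(s, day), tolerance = 1e-10)
    expect_equal(winter_desiccation_index(s, mx, p),
                 oracle_winter_desiccation(s, mx$t_site_max, day, TRUE),
                 tolerance = 1e-10)
    expect_equal(winter_desiccation_index(s, mx, p, "daytime_only"),
                 oracle_winter_desiccation(s, mx$t_site_max, day, FALSE),
                 tolerance = 1e-10)
    expect_equal(frost_index(s, mx, p),
                 oracle_frost(s, mx$t_site_max, mx$ws_site_max, day),
                 tolerance = 1e-10)
    expect_equal(insolation(s, p), oracle_insolation(s, day),
                 tolerance = 1e-10)
  }
})

test_that("indices scale and order as their formulas dictate", {
  set.seed(13)
  s <- random_series(n_days = 2)
  p <- partition_day_night(s)
  mx <- site_maxima(list(s))
  base_photo <- photoinhibition_index(s, mx, p)
  s_k <- s; s_k$solar_wm2 <- 3 * s$solar_wm2
  p_k <- partition_day_night(s_k) # same hours pass the threshold
  expect_equal(photoinhibition_index(s_k, mx, p_k), 3 * base_photo,
               tolerance = 1e-12)
  expect_equal(insolation(s_k, p_k), 3 * insolation(s, p),
               tolerance = 1e-12)
  # lowering any temperature weakly increases the cold-weighted indices
  s_c <- s; s_c$temp_c <- s$temp_c - 2
  expect_gte(photoinhibition_index(s_c, mx, p),
             photoinhibition_index(s, mx, p))
  expect_gte(winter_desiccation_index(s_c, mx, p),
             winter_desiccation_index(s, mx, p))
  expect_gte(frost_index(s_c, mx, p), frost_index(s, mx, p))
})

test_that("monthly summaries count extremes, frost hours and rain days", {
  s <- make_series(rep(5, 48), rep(2, 48), rep(60, 48), rep(0, 48),
                   rep(-40, 48))
  row <- monthly_summaries(s)
  expect_equal(row$temp_min, 5)
  expect_equal(row$temp_max, 5)
  expect_equal(row$frost_hours, 0)
  expect_equal(row$net_longwave, 40)

  temp <- rep(4, 31 * 24)
  temp[c(5:10, 100:105)] <- -1 # 12 sub-zero hours
  rain <- rep(0, 31); rain[c(2, 5, 9, 12, 20, 25, 30)] <- c(3, 0.1, 8, 1,
                                                            2, 5, 0.4)
  s2 <- make_series(temp, rep(2, 31 * 24), rep(60, 31 * 24),
                    rep(0, 31 * 24), rep(-40, 31 * 24), rain_daily = rain)
  row2 <- monthly_summaries(s2)
  expect_equal(row2$frost_hours, 12)
  expect_equal(row2$rain_days, 7)
  expect_equal(row2$temp_min, -1)

  # all-daytime series flags the longwave summary as undefined
  s3 <- make_series(rep(5, 24), rep(1, 24), rep(50, 24), rep(300, 24),
                    rep(200, 24))
  expect_warning(row3 <- monthly_summaries(s3), "longwave")
  expect_true(is.na(row3$net_longwave))
})

test_that("grouped index tables pick the month-appropriate desiccation", {
  set.seed(5)
  series <- list(random_series(2, "Jan", "S1", "p1"),
                 random_series(2, "Jan", "S1", "p2"),
                 random_series(2, "Jul", "S1", "p1"),
                 random_series(2, "Jul", "S1", "p2"))
  tabs <- topoclimate_tables(series)
  expect_equal(nrow(tabs$indices), 4)
  expect_equal(nrow(tabs$summaries), 4)
  jan1 <- tabs$indices[tabs$indices$month == "Jan" &
                         tabs$indices$point_id == "p1", ]
  mx <- site_maxima(series[1:2])
  p <- partition_day_night(series[[1]])
  expect_equal(jan1$desiccation, summer_desiccation_index(series[[1]], p))
  jul1 <- tabs$indices[tabs$indices$month == "Jul" &
                         tabs$indices$point_id == "p1", ]
  mxj <- site_maxima(series[3:4])
  pj <- partition_day_night(series[[3]])
  expect_equal(jul1$desiccation,
               winter_desiccation_index(series[[3]], mxj, pj))
})
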