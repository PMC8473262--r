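test_that("aggregation means concentrations, sums precipitation, is idempotent", {
  ts <- as.POSIXct("2019-07-01 10:00", tz = "UTC") + 0:3 * 900
  obs <- chla_obs(ts, "s1", c(10, 10, 20, 20))
  h <- aggregate_series(obs, "hourly")
  expect_equal(h$chla, 15)
  expect_equal(h$n, 4)

  w <- weather_records(as.POSIXct("2019-07-01", tz = "UTC") + 0:23 * 3600,
                       "s1", precip = 1, air_temp = 20)
  d <- aggregate_series(w, "daily")
  expect_equal(d$precip, 24)
  expect_equal(d$air_temp, 20)
  # idempotence: daily-aggregating a daily series is the identity
  d2 <- aggregate_series(d, "daily")
  expect_equal(as.data.frame(d2), as.data.frame(d))
})

test_that("diel relativization divides by the window maximum", {
  ts <- as.POSIXct("2019-07-01 09:00", tz = "UTC") + 0:7 * 3600
  p <- relativize_diel(data.frame(timestamp = ts, chla = rep(12, 8),
                                  site = "s1"))
  expect_equal(unlist(p[paste0("h", sprintf("%02d", 9:16))], use.names = FALSE),
               rep(1, 8))
  expect_true(p$complete)

  v <- c(10, 8, 6, 4, 4, 6, 8, 10)
  p2 <- relativize_diel(data.frame(timestamp = ts, chla = v, site = "s1"))
  expect_equal(unlist(p2[paste0("h", sprintf("%02d", 9:16))],
                      use.names = FALSE), v / 10)
  # invariance to positive scaling of the day's values
  p3 <- relativize_diel(data.frame(timestamp = ts, chla = 7.3 * v, site = "s1"))
  expect_equal(as.numeric(p3[paste0("h", sprintf("%02d", 9:16))]),
               as.numeric(p2[paste0("h", sprintf("%02d", 9:16))]))
  # incomplete and degenerate days
  p4 <- relativize_diel(data.frame(timestamp = ts[1:5], chla = v[1:5],
                                   site = "s1"))
  expect_false(p4$complete)
  expect_error(relativize_diel(data.frame(timestamp = ts, chla = 0,
                                          site = "s1")), "degenerate")
})

test_that("common_days keeps exactly the dates complete at every site", {
  ts <- as.POSIXct("2019-07-01 09:00", tz = "UTC") + 0:7 * 3600
  mk <- function(site, dates) do.call(rbind, lapply(dates, function(d)
    data.frame(timestamp = ts + as.numeric(as.Date(d) - as.Date("2019-07-01")) * 86400,
               site = site, chla = c(10, 8, 6, 4, 4, 6, 8, 10))))
  h <- rbind(mk("a", c("2019-07-01", "2019-07-02", "2019-07-03")),
             mk("b", c("2019-07-02", "2019-07-03")),
             mk("c", c("2019-07-01", "2019-07-02", "2019-07-03")))
  prof <- diel_profiles(chla_obs(h$timestamp, h$site, h$chla))
  kept <- common_days(prof)
  expect_setequal(as.character(unique(kept$date)),
                  c("2019-07-02", "2019-07-03"))
  expect_equal(nrow(kept), 6)
  # all sites complete -> identity
  expect_equal(nrow(common_days(prof[prof$date > as.Date("2019-07-01"), ])), 6)
})

test_that("antecedent features use strict 7-day windows and the meteorological convention", {
  ts <- as.POSIXct(paste(seq(as.Date("2019-07-01"), by = "day",
                             length.out = 20)), tz = "UTC")
  w <- weather_records(ts, "s1", air_temp = 20, wind_speed = 10,
                       wind_dir = 270, precip = 1, irradiance = 500,
                       resolution = "daily")
  f <- antecedent_features(w)
  expect_true(all(is.na(f$rain7[1:7])))       # boundary policy
  expect_equal(f$rain7[8:20], rep(7, 13))     # 1 mm/day over 7 days
  expect_equal(f$temp7[10], 20)
  expect_equal(f$u, rep(10, 20))              # westerly -> positive u
  expect_equal(f$v, rep(0, 20), tolerance = 1e-12)
  expect_true(all(f$rain7 >= f$rain, na.rm = TRUE))
  # a gap in the window propagates NA antecedents
  w2 <- weather_records(ts[-10], "s1", air_temp = 20, precip = 1,
                        resolution = "daily")
  f2 <- antecedent_features(w2)
  expect_true(all(is.na(f2$rain7[f2$date %in% (as.Date("2019-07-10") + 1:7)])))
})

test_that("vector-mean wind speed never exceeds scalar-mean wind speed", {
  set.seed(21)
  for (i in 1:20) {
    n <- 24
    speed <- runif(n, 0, 15)
    dir <- runif(n, 0, 360)
    uv <- lakechla:::wind_uv(speed, dir)
    expect_lte(sqrt(mean(uv$u)^2 + mean(uv$v)^2), mean(speed) + 1e-12)
  }
})

test_that("max-decline detection matches printed storm pairs and a brute-force scan", {
  printed <- rbind(
    data.frame(site = "trasimeno", date = as.Date(c("2019-07-27", "2019-07-28")),
               temp = c(32, 18.0)),
    data.frame(site = "vortsjarv", date = as.Date(c("2019-07-28", "2019-07-29")),
               temp = c(34.8, 15)),
    data.frame(site = "curonian", date = as.Date(c("2019-07-29", "2019-08-01")),
               temp = c(24.9, 15.5)))
  ev <- detect_max_decline(printed, window_days = 3)
  expect_equal(max(ev$decline), 19.8)
  expect_equal(ev$site[which.max(ev$decline)], "vortsjarv")
  expect_equal(ev$decline[ev$site == "trasimeno"], 14)
  expect_equal(ev$decline[ev$site == "curonian"], 9.4)
  expect_true(all(ev$trough_date > ev$peak_date))

  inc <- data.frame(site = "x", date = as.Date("2019-07-01") + 0:9,
                    temp = 1:10)
  expect_equal(detect_max_decline(inc)$decline, 0)

  set.seed(33)
  for (i in 1:10) {
    d <- data.frame(site = "x", date = as.Date("2019-07-01") + 0:19,
                    temp = rnorm(20, 20, 5))
    ev <- detect_max_decline(d, window_days = 3)
    expect_equal(ev$decline, brute_max_decline(d$date, d$temp, 3))
  }
})

test_that("match-up statistics recover known relationships", {
  x <- c(2, 5, 9, 14, 22)
  expect_equal(matchup_stats(x, x), list(r2 = 1, slope = 1, intercept = 0,
                                         n = 5))
  m2 <- matchup_stats(2 * x, x)
  expect_equal(m2$slope, 2)
  expect_equal(m2$r2, 1)
  expect_error(matchup_stats(c(1, 2, 3), c(4, 4, 4)), "zero variance")
  expect_error(matchup_stats(1:2, 1:2), "at least 3")
  set.seed(8)
  ref <- runif(29, 4, 120)
  est <- 0.9 * ref + rnorm(29, 0, 4)
  fit <- matchup_stats(est, ref)
  ci <- 0.9 + c(-4, 4) * 4 / (sd(ref) * sqrt(28))  # generous slope band
  expect_gt(fit$slope, ci[1]); expect_lt(fit$slope, ci[2])
  expect_gt(fit$r2, 0.8)
})
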