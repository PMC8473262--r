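quiet_cfg <- function(...) {
  scenario_config(weather_noise = list(temp_sd = 0, wind_sd = 0, rain_p = 0),
                  noise_cv = 0, ...)
}

test_that("generator is deterministic under a fixed seed", {
  cfg <- scenario_config(end = as.Date("2019-08-05"), seed = 9L)
  w1 <- generate_weather(cfg); w2 <- generate_weather(cfg)
  expect_identical(w1, w2)
  ct1 <- generate_chla_truth(cfg, w1)
  ct2 <- generate_chla_truth(cfg, w2)
  expect_identical(ct1$obs$chla, ct2$obs$chla)
})

test_that("zero-noise temperature without events is seasonal plus a pure diurnal cycle", {
  cfg <- quiet_cfg(heatwave = NULL, storm = NULL, end = as.Date("2019-07-15"))
  w <- generate_weather(cfg)$trasimeno
  daily_mean <- aggregate_series(w, "daily")$air_temp
  anom <- w$air_temp - rep(daily_mean, each = 24)
  # the diurnal anomaly is exactly 24 h periodic
  expect_equal(anom[1:24], anom[25:48], tolerance = 1e-12)
  expect_equal(max(abs(anom)), 4, tolerance = 1e-9)
  # rain absent without noise or storm
  expect_true(all(w$precip == 0))
})

test_that("storm drop construction yields the configured day-over-day decline", {
  cfg <- quiet_cfg(end = as.Date("2019-08-20"))
  for (site in c("trasimeno", "vortsjarv")) {
    w <- generate_weather(cfg)[[site]]
    td <- aggregate_series(w, "daily")
    dd <- -diff(td$air_temp)
    expect_equal(max(dd), 19.8, tolerance = 1e-9)
    expect_equal(as.Date(td$timestamp[which.max(dd)], tz = "UTC"),
                 cfg$storm$date - 1)
  }
  # storm wind spike reaches the configured peak
  w <- generate_weather(cfg)$trasimeno
  storm_day <- as.Date(w$timestamp, tz = "UTC") == cfg$storm$date
  expect_equal(max(w$wind_speed[storm_day]), cfg$storm$wind_peak)
  expect_equal(sum(w$precip[storm_day]), cfg$storm$rain_total)
  expect_error(scenario_config(storm = list(date = as.Date("2019-12-01"),
                                            temp_drop = 10, wind_peak = 10,
                                            rain_total = 10)),
               "storm date outside")
})

test_that("flat zero-noise days are constant at the daily level, step factor works", {
  cfg <- quiet_cfg(diel_shapes = list(
    trasimeno = c(concave = 0, convex = 0, flat = 1),
    curonian = c(concave = 0, convex = 0, flat = 1),
    vortsjarv = c(concave = 0, convex = 0, flat = 1)),
    end = as.Date("2019-08-10"))
  ct <- generate_chla_truth(cfg, generate_weather(cfg))
  o <- ct$obs[ct$obs$site == "trasimeno", ]
  day <- as.Date(o$timestamp, tz = "UTC")
  spread <- tapply(o$chla, day, function(v) diff(range(v)))
  expect_true(all(spread < 1e-12))
  tr <- ct$truth$daily[ct$truth$daily$site == "trasimeno", ]
  expect_equal(as.vector(tapply(o$chla, day, max)), tr$chla_true)
  # post-storm step factor present in the truth level
  pre <- tr$chla_true[tr$date == cfg$storm$date - 1]
  post <- tr$chla_true[tr$date == cfg$storm$date]
  surf_pre <- lakechla:::surface_value(cfg$response_surface, tr$doy[tr$date == cfg$storm$date - 1],
                                       tr$temp7[tr$date == cfg$storm$date - 1],
                                       tr$wind[tr$date == cfg$storm$date - 1])
  surf_post <- lakechla:::surface_value(cfg$response_surface, tr$doy[tr$date == cfg$storm$date],
                                        tr$temp7[tr$date == cfg$storm$date],
                                        tr$wind[tr$date == cfg$storm$date])
  expect_equal(post / surf_post / (pre / surf_pre), cfg$post_storm_step)
})

test_that("concave days dip at midday; depth follows irradiance and wind", {
  cfg <- quiet_cfg(diel_shapes = list(
    trasimeno = c(concave = 1, convex = 0, flat = 0),
    curonian = c(concave = 1, convex = 0, flat = 0),
    vortsjarv = c(concave = 0, convex = 1, flat = 0)),
    end = as.Date("2019-07-10"), heatwave = NULL, storm = NULL)
  ct <- generate_chla_truth(cfg, generate_weather(cfg))
  o <- ct$obs[ct$obs$site == "trasimeno", ]
  hourly <- aggregate_series(chla_obs(o$timestamp, o$site, o$chla), "hourly")
  prof <- diel_profiles(hourly)
  vals <- as.matrix(prof[, paste0("h", sprintf("%02d", 9:16))])
  expect_true(all(apply(vals, 1, which.min) %in% c(3, 4, 5)))  # 11:00-13:00
  # convex site peaks at midday instead
  o2 <- ct$obs[ct$obs$site == "vortsjarv", ]
  prof2 <- diel_profiles(aggregate_series(chla_obs(o2$timestamp, o2$site, o2$chla), "hourly"))
  vals2 <- as.matrix(prof2[, paste0("h", sprintf("%02d", 9:16))])
  expect_true(all(apply(vals2, 1, which.max) %in% c(3, 4, 5)))
})

test_that("noiseless forward spectra retrieve the generating truth; noise degrades it monotonically", {
  cfg <- quiet_cfg(end = as.Date("2019-07-08"), heatwave = NULL, storm = NULL)
  ct <- generate_chla_truth(cfg, generate_weather(cfg))
  rrs <- generate_rrs(ct$obs, cfg)
  got <- retrieve_chla(rrs$trasimeno)
  truth <- ct$obs$chla[ct$obs$site == "trasimeno"]
  expect_lt(max(abs(got$chla - truth) / truth), 1e-9)
  # Monte-Carlo: retrieval RMSE grows with multiplicative band noise
  rmse <- sapply(c(0.01, 0.05, 0.15), function(cv) {
    cfgn <- quiet_cfg(end = as.Date("2019-07-08"), rrs_noise_cv = cv,
                      heatwave = NULL, storm = NULL)
    rn <- generate_rrs(ct$obs, cfgn)
    gn <- retrieve_chla(rn$trasimeno)
    ok <- !is.na(gn$chla)
    sqrt(mean((gn$chla[ok] - truth[ok])^2))
  })
  expect_true(all(diff(rmse) > 0))
})

test_that("scenario export is reproducible and round-trips through the readers", {
  cfg <- scenario_config(end = as.Date("2019-07-14"), seed = 5L,
                         heatwave = NULL, storm = NULL)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- generate_scenario(cfg, d1)
  s2 <- generate_scenario(cfg, d2)
  m1 <- yaml::read_yaml(s1$manifest); m2 <- yaml::read_yaml(s2$manifest)
  expect_identical(m1$config_hash, m2$config_hash)
  expect_identical(m1$seed, m2$seed)
  for (site in cfg$sites$name) {
    back <- read_rrs_table(s1$files[[paste0("rrs_", site)]], site)
    rrs <- generate_rrs(s1$obs, cfg)[[site]]
    expect_equal(back$rrs, rrs$rrs, tolerance = 1e-10)
    wback <- read_weather_table(s1$files[[paste0("weather_", site)]], site)
    expect_equal(nrow(wback), nrow(generate_weather(cfg)[[site]]))
  }
  # the daily-resolution site is emitted and re-read as daily
  wcur <- read_weather_table(s1$files[["weather_curonian"]], "curonian")
  expect_true(all(wcur$resolution == "daily"))
})
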