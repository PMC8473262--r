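#' @title Synthetic multi-site scenario generator
#' @description Generates weather, chlorophyll-a truth and forward-modelled
#'   reflectance spectra for a configurable multi-site summer scenario with the
#'   statistical structure the downstream analysis assumes: contrasting
#'   climates, concave/convex diel chlorophyll patterns modulated by irradiance
#'   and wind, a mid-summer heatwave terminated by a storm, a post-storm
#'   step-change in chlorophyll, and mixed hourly/daily weather resolution.
#' @name lakechla-synthetic
NULL

# evaluate-with-seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Scenario configuration
#'
#' Defaults reproduce the structure of the 2019 study window: three sites,
#' 1 July to 30 September, 15-minute sampling, a week-long heatwave ending in
#' a storm on 28 July with a 19.8 degC day-over-day temperature drop, and a
#' two-fold post-storm chlorophyll step at the lake sites.
#'
#' @param sites site registry rows ([site_registry()]).
#' @param start,end scenario date range (`Date`).
#' @param cadence_minutes reflectance sampling interval, minutes (>= 1).
#' @param heatwave list `(start, length_days, amplitude)` or NULL for none.
#' @param storm list `(date, temp_drop, wind_peak, rain_total)` or NULL.
#' @param diel_shapes named list (per site) of mixture weights over
#'   `concave`, `convex`, `flat`; each must sum to 1.
#' @param response_surface list `(name, coefficients)` linking daily
#'   chlorophyll to day-of-year, 7-day antecedent temperature and wind.
#'   Available surfaces: `gaussian_seasonal` (Gaussian seasonal peak times
#'   log-linear temperature and wind effects) and `constant`.
#' @param noise_cv lognormal coefficient of variation of daily chlorophyll.
#' @param post_storm_step multiplicative chlorophyll step after the storm.
#' @param depth_coef diel-depth rule `c(d0, d1, d2)`:
#'   `depth = d0 + d1 * irradiance - d2 * wind`, clipped to `[0, 0.8]` —
#'   encodes the observed association of concave (midday-dip, quenching-like)
#'   patterns with high irradiance and low wind.
#' @param weather_noise list `(temp_sd, wind_sd, rain_p)`: AR(1) innovation
#'   SDs for temperature and wind and the background hourly rain probability.
#'   Set all to 0 for deterministic weather.
#' @param rrs_noise_cv multiplicative spectral noise CV (0 = noiseless, in
#'   which case retrieval reproduces truth to machine precision).
#' @param daily_sites sites whose emitted weather is daily-resolution only
#'   (emulates stations that report daily temperature).
#' @param seed integer RNG seed.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(sites = site_registry(),
                            start = as.Date("2019-07-01"),
                            end = as.Date("2019-09-30"),
                            cadence_minutes = 15,
                            heatwave = list(start = as.Date("2019-07-21"),
                                            length_days = 7, amplitude = 8),
                            storm = list(date = as.Date("2019-07-28"),
                                         temp_drop = 19.8, wind_peak = 12,
                                         rain_total = 30),
                            diel_shapes = NULL,
                            response_surface = list(
                              name = "gaussian_seasonal",
                              coefficients = c(a0 = 20, doy_mu = 250,
                                               doy_sigma = 35, b_temp = 0.05,
                                               b_wind = -0.05)),
                            noise_cv = 0.1,
                            post_storm_step = 2.0,
                            depth_coef = c(d0 = 0.1, d1 = 0.0015, d2 = 0.03),
                            weather_noise = list(temp_sd = 0.8, wind_sd = 0.8,
                                                 rain_p = 0.04),
                            rrs_noise_cv = 0,
                            daily_sites = "curonian",
                            seed = 42L) {
  validate_sites(sites)
  if (cadence_minutes < 1) stop("config error: cadence below 1 minute",
                                call. = FALSE)
  if (noise_cv < 0) stop("config error: noise_cv must be >= 0", call. = FALSE)
  if (end < start) stop("config error: end before start", call. = FALSE)
  if (is.null(diel_shapes)) {
    w <- list(c(concave = 0.6, convex = 0.3, flat = 0.1),
              c(concave = 0.3, convex = 0.5, flat = 0.2),
              c(concave = 0.5, convex = 0.3, flat = 0.2))
    diel_shapes <- stats::setNames(w[(seq_len(nrow(sites)) - 1L) %% 3L + 1L],
                                   sites$name)
  }
  for (s in sites$name) {
    ws <- diel_shapes[[s]]
    if (is.null(ws) || abs(sum(ws) - 1) > 1e-8)
      stop("config error: diel shape weights for '", s, "' must sum to 1",
           call. = FALSE)
  }
  if (!is.null(storm) && (storm$date < start || storm$date > end))
    stop("config error: storm date outside date_range", call. = FALSE)
  if (!is.null(heatwave) &&
      (heatwave$start < start - 30 || heatwave$start > end))
    stop("config error: heatwave start outside date_range", call. = FALSE)
  structure(list(sites = sites, start = start, end = end,
                 cadence_minutes = cadence_minutes, heatwave = heatwave,
                 storm = storm, diel_shapes = diel_shapes,
                 response_surface = response_surface, noise_cv = noise_cv,
                 post_storm_step = post_storm_step, depth_coef = depth_coef,
                 weather_noise = weather_noise, rrs_noise_cv = rrs_noise_cv,
                 daily_sites = daily_sites, seed = as.integer(seed)),
            class = "scenario_config")
}

site_seed <- function(cfg, site) {
  cfg$seed + 1000L * match(site, cfg$sites$name)
}

# noise-free daily-mean temperature path for one site (degC)
.daily_temp_base <- function(cfg, site, dates) {
  lat <- cfg$sites$latitude[cfg$sites$name == site]
  doy <- as.integer(format(dates, "%j"))
  t0 <- 26 - 0.45 * (lat - 43.13)            # warmer south
  base <- t0 + 4 * cos(2 * pi * (doy - 205) / 365)
  if (!is.null(cfg$heatwave)) {
    hw <- cfg$heatwave
    rel <- as.numeric(dates - hw$start)
    ramp <- pmax(0, pmin(1, rel + 1, hw$length_days - rel))
    base <- base + hw$amplitude * ramp
  }
  base
}

# post-storm temperature deficit, constructed so the realized day-over-day
# decline of the daily mean equals storm$temp_drop exactly at zero noise
.storm_deficit <- function(cfg, site, dates) {
  if (is.null(cfg$storm)) return(numeric(length(dates)))
  base <- .daily_temp_base(cfg, site, dates)
  s <- match(cfg$storm$date, dates)
  if (is.na(s) || s < 2L) return(numeric(length(dates)))
  natural <- base[s - 1L] - base[s]
  delta <- cfg$storm$temp_drop - natural
  rel <- as.numeric(dates - cfg$storm$date)
  ifelse(rel >= 0, delta * exp(-rel / 5), 0)
}

#' Generate synthetic weather
#'
#' Per site: temperature = seasonal sinusoid + diurnal cycle + heatwave block
#' + storm drop + AR(1) noise; wind = AR(1) >= 0 with a storm-day spike to
#' `wind_peak`; rain = intermittent background pulses plus the storm's
#' `rain_total` concentrated on the storm day; irradiance = clear-sky diurnal
#' curve damped on rainy hours. Deterministic given the seed; sites use
#' independent sub-seeded streams.
#'
#' @param cfg [scenario_config()].
#' @return named list of [weather_records], one per site; sites listed in
#'   `cfg$daily_sites` are aggregated to daily resolution before emission.
#' @export
generate_weather <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  dates <- seq(cfg$start, cfg$end, by = "day")
  out <- list()
  for (site in cfg$sites$name) {
    out[[site]] <- with_seed(site_seed(cfg, site) + 1L,
                             .weather_one_site(cfg, site, dates))
  }
  out
}

.weather_one_site <- function(cfg, site, dates) {
  nh <- length(dates) * 24L
  ts <- as.POSIXct(paste(rep(dates, each = 24L),
                         sprintf("%02d:00:00", rep(0:23, length(dates)))),
                   tz = "UTC")
  hour <- rep(0:23, length(dates))
  day_idx <- rep(seq_along(dates), each = 24L)
  lat <- cfg$sites$latitude[cfg$sites$name == site]
  doy <- as.integer(format(dates, "%j"))[day_idx]

  base <- .daily_temp_base(cfg, site, dates)[day_idx]
  deficit <- .storm_deficit(cfg, site, dates)[day_idx]
  diurnal <- 4 * cos(2 * pi * (hour - 14) / 24)
  temp_noise <- ar1(nh, phi = 0.7, sd = cfg$weather_noise$temp_sd)
  air_temp <- base + diurnal - deficit + temp_noise

  wind_mu <- 3
  wind <- pmax(0, wind_mu + ar1(nh, phi = 0.8, sd = cfg$weather_noise$wind_sd))
  if (!is.null(cfg$storm)) {
    on_storm <- dates[day_idx] == cfg$storm$date
    spike <- (cfg$storm$wind_peak - wind_mu) * exp(-0.5 * ((hour - 12) / 4)^2)
    wind[on_storm] <- pmax(wind[on_storm], wind_mu + spike[on_storm])
  }

  wdir <- (270 + ar1(nh, phi = 0.9, sd = 4 * cfg$weather_noise$wind_sd)) %% 360

  rain <- numeric(nh)
  p <- cfg$weather_noise$rain_p
  if (p > 0) {
    wet <- stats::runif(nh) < p
    rain[wet] <- stats::rgamma(sum(wet), shape = 0.7, scale = 3)
  }
  if (!is.null(cfg$storm)) {
    on_storm <- dates[day_idx] == cfg$storm$date
    w <- pmax(0, 1 - abs(hour - 12) / 8)
    w <- w / sum(w[1:24])
    rain[on_storm] <- rain[on_storm] + cfg$storm$rain_total * w[on_storm]
  }

  s0 <- 900 - 5 * (lat - 43.13)
  seas <- 0.75 + 0.25 * cos(2 * pi * (doy - 172) / 365)
  irr <- s0 * seas * pmax(0, sin(pi * (hour - 6) / 12))
  irr[rain > 0] <- irr[rain > 0] * 0.3

  w <- weather_records(ts, site, air_temp = air_temp, wind_speed = wind,
                       wind_dir = wdir, precip = rain, irradiance = irr,
                       resolution = "hourly")
  if (site %in% cfg$daily_sites) w <- aggregate_weather_daily(w)
  w
}

ar1 <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, sd = sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

surface_value <- function(surface, doy, temp7, wind) {
  co <- surface$coefficients
  switch(surface$name,
         gaussian_seasonal =
           co[["a0"]] * exp(-0.5 * ((doy - co[["doy_mu"]]) / co[["doy_sigma"]])^2) *
           exp(co[["b_temp"]] * (temp7 - 20)) * exp(co[["b_wind"]] * wind),
         constant = rep_len(co[["a0"]], length(doy)),
         stop("unknown response surface '", surface$name, "'", call. = FALSE))
}

#' Generate chlorophyll-a truth and high-frequency concentrations
#'
#' Daily level = response surface (day-of-year, 7-day antecedent temperature,
#' daily wind) times the post-storm step times mean-1 lognormal noise.
#' Within-day modulation follows the day's diel shape: `concave` days dip at
#' midday (depth increasing with irradiance and decreasing with wind — the
#' quenching analogue), `convex` days peak at midday, `flat` days stay at the
#' daily level. All concentrations are positive.
#'
#' @param cfg [scenario_config()].
#' @param weather output of [generate_weather()] (or compatible list).
#' @return list with `truth` (class `scenario_truth`: per-site-day level,
#'   shape label, depth, generating surface, event dates) and `obs`
#'   (a [chla_obs] table at cadence over the 06:00-18:00 daylight window).
#' @export
generate_chla_truth <- function(cfg, weather) {
  stopifnot(inherits(cfg, "scenario_config"))
  dates <- seq(cfg$start, cfg$end, by = "day")
  truth <- list(); obs <- list()
  sdlog <- sqrt(log(1 + cfg$noise_cv^2))
  for (site in cfg$sites$name) {
    w <- weather[[site]]
    if (is.null(w)) stop("weather missing for site ", site, call. = FALSE)
    wd <- aggregate_weather_daily(w)
    if (!all(dates %in% as.Date(wd$timestamp, tz = "UTC")))
      stop("weather does not cover the scenario date range", call. = FALSE)
    i <- match(dates, as.Date(wd$timestamp, tz = "UTC"))
    temp_d <- wd$air_temp[i]; wind_d <- wd$wind_speed[i]
    irr_d <- wd$irradiance[i]
    # strictly-antecedent 7-day temperature mean; expanding window at the
    # start of the scenario so the truth surface has no missing values
    temp7 <- vapply(seq_along(dates), function(k) {
      if (k == 1L) temp_d[1] else mean(temp_d[max(1, k - 7):(k - 1)])
    }, numeric(1))
    doy <- as.integer(format(dates, "%j"))

    res <- with_seed(site_seed(cfg, site) + 2L, {
      level <- surface_value(cfg$response_surface, doy, temp7, wind_d)
      if (!is.null(cfg$storm))
        level <- level * ifelse(dates >= cfg$storm$date, cfg$post_storm_step, 1)
      if (cfg$noise_cv > 0)
        level <- level * stats::rlnorm(length(level), -sdlog^2 / 2, sdlog)
      shape <- vapply(seq_along(dates), function(k)
        sample(names(cfg$diel_shapes[[site]]), 1,
               prob = cfg$diel_shapes[[site]]), character(1))
      list(level = level, shape = shape)
    })
    dc <- cfg$depth_coef
    depth <- pmin(0.8, pmax(0, dc[["d0"]] + dc[["d1"]] * irr_d -
                              dc[["d2"]] * wind_d))
    depth[res$shape == "flat"] <- 0

    truth[[site]] <- data.frame(site = site, date = dates, doy = doy,
                                chla_true = res$level,
                                diel_shape = res$shape, depth = depth,
                                temp7 = temp7, wind = wind_d,
                                stringsAsFactors = FALSE)

    step_min <- cfg$cadence_minutes
    tod <- seq(6 * 60, 18 * 60, by = step_min) / 60   # hours, daylight window
    hod <- rep(tod, length(dates))
    di <- rep(seq_along(dates), each = length(tod))
    g <- exp(-0.5 * ((hod - 12) / 3)^2)
    mod <- ifelse(res$shape[di] == "convex", 1 - depth[di] * (1 - g),
                  1 - depth[di] * g)   # concave and flat (depth 0)
    ts <- as.POSIXct(paste(dates[di]), tz = "UTC") + hod * 3600
    obs[[site]] <- data.frame(timestamp = ts, site = site,
                              chla = res$level[di] * mod,
                              stringsAsFactors = FALSE)
  }
  truth_df <- do.call(rbind, truth); rownames(truth_df) <- NULL
  obs_df <- do.call(rbind, obs)
  events <- list(
    heatwave_peak = if (!is.null(cfg$heatwave))
      cfg$heatwave$start + cfg$heatwave$length_days - 1 else NULL,
    storm_date = if (!is.null(cfg$storm)) cfg$storm$date else NULL)
  list(truth = structure(list(daily = truth_df,
                              surface = cfg$response_surface,
                              events = events),
                         class = "scenario_truth"),
       obs = chla_obs(obs_df$timestamp, obs_df$site, obs_df$chla))
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat(sprintf("<scenario_truth> %d site-days, surface '%s'\n",
              nrow(x$daily), x$surface$name))
  invisible(x)
}

#' Forward-model reflectance spectra from chlorophyll-a series
#'
#' Builds full 350-900 nm spectra on the instrument's 4.6 nm ladder augmented
#' with the exact 672/704/776 nm algorithm bands, so that noiseless spectra
#' retrieve the generating concentration to machine precision. Off-band
#' structure is a smooth spline through fixed anchor reflectances and carries
#' no signal.
#'
#' @param obs [chla_obs] table for one or more sites (chla > 0).
#' @param cfg [scenario_config()] (provides `rrs_noise_cv` and seed).
#' @param coef [retrieval_coefficients].
#' @param bb,rrs672 backscatter (m^-1) and red-band reflectance (sr^-1)
#'   assumed by the forward model.
#' @return named list of [rrs_records], one per site.
#' @export
generate_rrs <- function(obs, cfg, coef = retrieval_coefficients(),
                         bb = 0.35, rrs672 = 0.010) {
  stopifnot(inherits(obs, "chla_obs"))
  grid <- sort(unique(c(seq(350, 900, by = 4.6), 672, 704, 776)))
  anchors_wl <- c(350, 450, 550, 620, 672, 704, 740, 776, 850, 900)
  anchors_base <- c(0.002, 0.004, 0.008, 0.006, NA, NA, 0.004, NA,
                    0.0015, 0.001)
  out <- list()
  for (site in unique(obs$site)) {
    o <- obs[obs$site == site & !is.na(obs$chla), , drop = FALSE]
    fw <- forward_rrs(o$chla, bb = bb, rrs672 = rrs672, coef = coef)
    spec <- matrix(0, nrow(o), length(grid))
    for (r in seq_len(nrow(o))) {
      ay <- anchors_base
      ay[anchors_wl == 672] <- fw$rrs672[r]
      ay[anchors_wl == 704] <- fw$rrs704[r]
      ay[anchors_wl == 776] <- fw$rrs776[r]
      spec[r, ] <- pmax(1e-6, stats::spline(anchors_wl, ay, xout = grid,
                                            method = "natural")$y)
    }
    # spline knots coincide with grid channels at the algorithm bands, so the
    # three signal bands are exact
    for (b in c(672, 704, 776))
      spec[, grid == b] <- fw[[paste0("rrs", b)]]
    if (cfg$rrs_noise_cv > 0) {
      spec <- with_seed(site_seed(cfg, site) + 3L,
                        spec * matrix(stats::rnorm(length(spec), 1,
                                                   cfg$rrs_noise_cv),
                                      nrow(spec)))
      spec <- pmax(spec, 1e-7)
    }
    out[[site]] <- rrs_records(o$timestamp, site, grid, spec)
  }
  out
}

# deterministic polynomial hash of the config text (manifest fingerprint)
config_hash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Generate a full scenario on disk
#'
#' Writes per-site weather and reflectance CSVs in the package's interchange
#' formats, the truth tables, and a manifest recording the seed and a config
#' hash.
#'
#' @param cfg [scenario_config()].
#' @param out_dir writable output directory (created if absent).
#' @return list with `truth`, `obs`, `files` (named character vector) and
#'   `manifest` path, invisibly.
#' @export
generate_scenario <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  weather <- generate_weather(cfg)
  ct <- generate_chla_truth(cfg, weather)
  rrs <- generate_rrs(ct$obs, cfg)
  files <- character(0)
  for (site in cfg$sites$name) {
    f <- file.path(out_dir, paste0("weather_", site, ".csv"))
    write_table(weather[[site]], f); files[paste0("weather_", site)] <- f
    f <- file.path(out_dir, paste0("rrs_", site, ".csv"))
    write_table(rrs[[site]], f); files[paste0("rrs_", site)] <- f
  }
  f <- file.path(out_dir, "chla_truth_obs.csv")
  write_table(ct$obs, f); files["chla_truth_obs"] <- f
  f <- file.path(out_dir, "truth_daily.csv")
  write_table(ct$truth$daily, f); files["truth_daily"] <- f
  cfg_txt <- yaml::as.yaml(config_to_plain(cfg))
  manifest <- list(seed = cfg$seed, config_hash = config_hash(cfg_txt),
                   files = as.list(files))
  mf <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, mf)
  invisible(list(truth = ct$truth, obs = ct$obs, files = files,
                 manifest = mf))
}

# plain-list (YAML-safe) view of a scenario config
config_to_plain <- function(cfg) {
  pl <- unclass(cfg)
  pl$sites <- as.list(stats::setNames(
    paste(pl$sites$latitude, pl$sites$longitude), pl$sites$name))
  for (f in c("start", "end")) pl[[f]] <- as.character(pl[[f]])
  if (!is.null(pl$heatwave)) pl$heatwave$start <- as.character(pl$heatwave$start)
  if (!is.null(pl$storm)) pl$storm$date <- as.character(pl$storm$date)
  pl$response_surface$coefficients <-
    as.list(pl$response_surface$coefficients)
  pl$depth_coef <- as.list(pl$depth_coef)
  pl$diel_shapes <- lapply(pl$diel_shapes, as.list)
  pl
}
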