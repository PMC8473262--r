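#' @title Aggregation, diel profiles, antecedent features and event detection
#' @name lakechla-features
NULL

floor_bin <- function(ts, resolution) {
  switch(resolution,
         hourly = as.POSIXct(trunc(ts, "hours"), tz = "UTC"),
         daily = as.POSIXct(format(ts, "%Y-%m-%d"), tz = "UTC"),
         stop("usage error: unknown resolution '", resolution, "'",
              call. = FALSE))
}

#' Aggregate observations to hourly or daily bins
#'
#' Arithmetic mean per half-open bin `[start, start + delta)` for
#' concentrations and most weather variables; precipitation is summed; wind
#' direction is vector-averaged. Bins with no data are absent from the output
#' rather than zero.
#'
#' @param x a [chla_obs] or [weather_records] table.
#' @param resolution `"hourly"` or `"daily"`.
#' @return For `chla_obs`: data.frame `site`, `timestamp` (bin start),
#'   `chla`, `n`. For `weather_records`: a [weather_records] table at the bin
#'   resolution.
#' @export
aggregate_series <- function(x, resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  UseMethod("aggregate_series")
}

#' @export
aggregate_series.chla_obs <- function(x, resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  d <- x[!is.na(x$chla), , drop = FALSE]
  bin <- floor_bin(d$timestamp, resolution)
  key <- paste(d$site, format_utc(bin))
  agg <- do.call(rbind, lapply(split(seq_len(nrow(d)), key), function(i)
    data.frame(site = d$site[i[1]], timestamp = bin[i[1]],
               chla = mean(d$chla[i]), n = length(i),
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$site, agg$timestamp), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
aggregate_series.weather_records <- function(x,
                                             resolution = c("daily", "hourly")) {
  resolution <- match.arg(resolution)
  bin <- floor_bin(x$timestamp, resolution)
  site <- x$site[1]
  mean_ <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sum_ <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  pieces <- lapply(split(seq_len(nrow(x)), format_utc(bin)), function(i) {
    uv <- wind_uv(x$wind_speed[i], x$wind_dir[i])
    dir <- uv_to_dir(mean_(uv$u), mean_(uv$v))
    data.frame(timestamp = bin[i[1]],
               air_temp = mean_(x$air_temp[i]),
               wind_speed = mean_(x$wind_speed[i]),
               wind_dir = dir,
               precip = sum_(x$precip[i]),
               irradiance = mean_(x$irradiance[i]))
  })
  d <- do.call(rbind, pieces)
  d <- d[order(d$timestamp), , drop = FALSE]
  weather_records(d$timestamp, site, air_temp = d$air_temp,
                  wind_speed = d$wind_speed, wind_dir = d$wind_dir,
                  precip = d$precip, irradiance = d$irradiance,
                  resolution = resolution)
}

aggregate_weather_daily <- function(w) {
  if (nrow(w) > 0 && all(w$resolution == "daily")) return(w)
  aggregate_series(w, "daily")
}

#' Broadcast daily weather to hourly records
#'
#' Stations that only report daily values are broadcast to all 24 hours of
#' the day when hourly features are required; the result is flagged via the
#' `broadcast` attribute.
#'
#' @param w daily-resolution [weather_records].
#' @return hourly [weather_records] with `attr(, "broadcast") = TRUE`.
#' @export
broadcast_hourly <- function(w) {
  stopifnot(inherits(w, "weather_records"))
  if (any(w$resolution == "hourly")) return(w)
  idx <- rep(seq_len(nrow(w)), each = 24L)
  ts <- rep(floor_bin(w$timestamp, "daily"), each = 24L) + 3600 * rep(0:23, nrow(w))
  out <- weather_records(ts, w$site[1], air_temp = w$air_temp[idx],
                         wind_speed = w$wind_speed[idx],
                         wind_dir = w$wind_dir[idx],
                         precip = w$precip[idx] / 24,
                         irradiance = w$irradiance[idx],
                         resolution = "hourly")
  attr(out, "broadcast") <- TRUE
  out
}

# meteorological from-direction convention: a westerly wind (dir = 270)
# blows toward the east, u = +speed, v = 0
wind_uv <- function(speed, dir) {
  rad <- dir * pi / 180
  list(u = -speed * sin(rad), v = -speed * cos(rad))
}

uv_to_dir <- function(u, v) {
  if (is.na(u) || is.na(v) || (u == 0 && v == 0)) return(NA_real_)
  (atan2(-u, -v) * 180 / pi) %% 360
}

#' Relativize one site-day of hourly chlorophyll to a diel profile
#'
#' The diel window is the 8 inclusive hourly bins 09:00-16:00 UTC; each bin is
#' divided by the day's maximum over the window so the daily pattern rather
#' than the absolute concentration is represented. A complete profile has
#' maximum exactly 1.
#'
#' @param hourly data.frame with `timestamp` (hour starts, UTC) and `chla`
#'   for a single site-day (as produced by [aggregate_series()]).
#' @return one-row data.frame: `site`, `date`, `h09` .. `h16`, `complete`.
#' @export
relativize_diel <- function(hourly) {
  stopifnot(all(c("timestamp", "chla") %in% names(hourly)))
  hr <- as.integer(format(hourly$timestamp, "%H", tz = "UTC"))
  keep <- hr >= 9 & hr <= 16 & !is.na(hourly$chla)
  if (!any(keep))
    stop("degenerate day: no values in the 09:00-16:00 window", call. = FALSE)
  v <- rep(NA_real_, 8)
  v[hr[keep] - 8L] <- hourly$chla[keep]
  mx <- max(v, na.rm = TRUE)
  if (mx <= 0) stop("degenerate day: daily maximum <= 0", call. = FALSE)
  out <- data.frame(site = if ("site" %in% names(hourly)) hourly$site[1] else NA,
                    date = as.Date(hourly$timestamp[1], tz = "UTC"),
                    stringsAsFactors = FALSE)
  out[paste0("h", sprintf("%02d", 9:16))] <- as.list(v / mx)
  out$complete <- !anyNA(v)
  out
}

#' Build diel profiles for every site-day
#'
#' @param hourly hourly-aggregated chlorophyll (output of
#'   [aggregate_series()] at `"hourly"`).
#' @return data.frame of class `diel_profiles`, one row per site-day, ordered
#'   chronologically by (date, site); this row order defines the 1-based row
#'   numbers used for cluster group numbering.
#' @export
diel_profiles <- function(hourly) {
  day <- as.Date(hourly$timestamp, tz = "UTC")
  keys <- split(seq_len(nrow(hourly)), paste(day, hourly$site))
  rows <- lapply(keys, function(i)
    tryCatch(relativize_diel(hourly[i, , drop = FALSE]),
             error = function(e) NULL))
  d <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  d <- d[order(d$date, d$site), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("diel_profiles", "data.frame")
  d
}

#' Keep only dates observed at every site
#'
#' Balanced-comparison filter: a date is retained only if every listed site
#' has a complete diel profile on that date.
#'
#' @param profiles a `diel_profiles` table.
#' @param sites site names that must all be present (default: all sites
#'   appearing in `profiles`).
#' @return filtered `diel_profiles`.
#' @export
common_days <- function(profiles, sites = unique(profiles$site)) {
  ok <- profiles$complete & profiles$site %in% sites
  tab <- table(profiles$date[ok], profiles$site[ok])
  full <- rownames(tab)[rowSums(tab > 0) == length(sites)]
  out <- profiles[ok & as.character(profiles$date) %in% full, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diel_profiles", "data.frame")
  out
}

#' Daily features with seven-day antecedent windows
#'
#' Joins daily chlorophyll with daily weather and derives the antecedent
#' features: seven-day rain total, seven-day mean wind speed and temperature,
#' and the wind vector components `u = -speed * sin(dir)`,
#' `v = -speed * cos(dir)` (meteorological from-direction, so a westerly wind
#' has positive `u`), vector-averaged per day then windowed. The antecedent
#' window is the 7 days strictly before the index date; a window with any
#' missing day yields a missing antecedent value.
#'
#' @param weather a [weather_records] table for one site (hourly or daily).
#' @param chla_daily daily-aggregated chlorophyll for the same site
#'   (columns `site`, `timestamp`, `chla`), or NULL.
#' @return data.frame of class `daily_features`: `date`, `site`,
#'   `chla_daily`, `doy`, `temp`, `temp7`, `rain`, `rain7`, `wind`, `wind7`,
#'   `u`, `v`, `u7`, `v7`, `irradiance`.
#' @export
antecedent_features <- function(weather, chla_daily = NULL) {
  stopifnot(inherits(weather, "weather_records"))
  site <- weather$site[1]
  uv <- wind_uv(weather$wind_speed, weather$wind_dir)
  day <- as.Date(weather$timestamp, tz = "UTC")
  mean_ <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  sum_ <- function(v) if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
  per_day <- lapply(split(seq_len(nrow(weather)), day), function(i)
    data.frame(temp = mean_(weather$air_temp[i]),
               rain = sum_(weather$precip[i]),
               wind = mean_(weather$wind_speed[i]),
               u = mean_(uv$u[i]), v = mean_(uv$v[i]),
               irradiance = mean_(weather$irradiance[i])))
  wd <- do.call(rbind, per_day)
  wd_dates <- as.Date(rownames(wd))

  dates <- seq(min(wd_dates), max(wd_dates), by = "day")
  idx <- match(dates, wd_dates)
  col <- function(nm) wd[[nm]][idx]
  d <- data.frame(date = dates, site = site, chla_daily = NA_real_,
                  doy = as.integer(format(dates, "%j")),
                  temp = col("temp"), rain = col("rain"), wind = col("wind"),
                  u = col("u"), v = col("v"), irradiance = col("irradiance"),
                  stringsAsFactors = FALSE)
  if (!is.null(chla_daily)) {
    cd <- chla_daily[chla_daily$site == site, , drop = FALSE]
    d$chla_daily <- cd$chla[match(dates, as.Date(cd$timestamp, tz = "UTC"))]
  }
  window_stat <- function(vals, fun) {
    vapply(seq_along(dates), function(k) {
      if (k <= 7L) return(NA_real_)
      w <- vals[(k - 7L):(k - 1L)]
      if (anyNA(w)) NA_real_ else fun(w)
    }, numeric(1))
  }
  d$temp7 <- window_stat(d$temp, mean)
  d$rain7 <- window_stat(d$rain, sum)
  d$wind7 <- window_stat(d$wind, mean)
  d$u7 <- window_stat(d$u, mean)
  d$v7 <- window_stat(d$v, mean)
  d <- d[, c("date", "site", "chla_daily", "doy", "temp", "temp7", "rain",
             "rain7", "wind", "wind7", "u", "v", "u7", "v7", "irradiance")]
  class(d) <- c("daily_features", "data.frame")
  d
}

#' Largest short-window temperature decline per site
#'
#' Finds, for each site, the (peak, trough) day pair maximizing
#' `peak_temp - trough_temp` with the trough at most `window_days` after the
#' peak — the quantification of a heatwave-terminating storm. Ties are broken
#' by the earliest peak date. A monotonically increasing series reports a
#' decline of 0.
#'
#' @param temp_daily data.frame with `site`, `date`, `temp` (daily degC).
#' @param window_days maximum days from peak to trough (default 3).
#' @return data.frame of class `event_report`: one row per site with
#'   `peak_date`, `peak_temp`, `trough_date`, `trough_temp`, `decline`,
#'   `window_days`; sites with no usable data are omitted.
#' @export
detect_max_decline <- function(temp_daily, window_days = 3) {
  stopifnot(all(c("site", "date", "temp") %in% names(temp_daily)))
  out <- lapply(split(temp_daily, temp_daily$site), function(d) {
    d <- d[!is.na(d$temp), , drop = FALSE]
    d <- d[order(d$date), , drop = FALSE]
    if (nrow(d) < 2L) return(NULL)
    best <- NULL
    for (i in seq_len(nrow(d) - 1L)) {
      lag <- as.numeric(d$date - d$date[i])
      for (j in which(lag > 0 & lag <= window_days)) {
        dec <- d$temp[i] - d$temp[j]
        if (is.null(best) || dec > best$decline) {
          best <- list(peak = i, trough = j, decline = dec)
        }
      }
    }
    if (is.null(best)) return(NULL)
    data.frame(site = d$site[1],
               peak_date = d$date[best$peak], peak_temp = d$temp[best$peak],
               trough_date = d$date[best$trough],
               trough_temp = d$temp[best$trough],
               decline = max(0, best$decline), window_days = window_days,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(NULL)
  rownames(out) <- NULL
  class(out) <- c("event_report", "data.frame")
  out
}

#' Match-up validation statistics
#'
#' Ordinary least squares of station estimates on laboratory reference
#' concentrations, the standard validation summary for a retrieval exercise.
#'
#' @param estimate,reference paired concentrations, mg m^-3 (n >= 3).
#' @return list `r2` (squared Pearson correlation), `slope`, `intercept`,
#'   `n`.
#' @export
matchup_stats <- function(estimate, reference) {
  keep <- !is.na(estimate) & !is.na(reference)
  estimate <- estimate[keep]; reference <- reference[keep]
  if (length(estimate) < 3L) stop("need at least 3 match-up pairs",
                                  call. = FALSE)
  if (stats::var(reference) == 0)
    stop("degenerate match-up: reference has zero variance", call. = FALSE)
  fit <- stats::lm(estimate ~ reference)
  list(r2 = stats::cor(estimate, reference)^2,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(estimate))
}
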