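#' @title Record containers and delimited-table input/output
#' @description All on-disk interchange uses comma-separated text with ISO-8601
#'   UTC timestamps and period decimal separators. Readers sort by timestamp on
#'   ingest so downstream results are invariant to input row order.
#' @name lakechla-io
NULL

.ts_formats <- c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                 "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")

#' Parse UTC timestamps
#' @param x character vector of ISO-8601-ish timestamps.
#' @return POSIXct in UTC; NA where unparseable.
#' @keywords internal
parse_utc <- function(x) {
  as.POSIXct(as.character(x), tz = "UTC", tryFormats = .ts_formats,
             optional = TRUE)
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Construct a reflectance-spectra record set
#'
#' An `rrs_records` object holds a time series of remote-sensing reflectance
#' spectra Rrs(lambda) for one site on a common wavelength grid.
#'
#' @param timestamp POSIXct (UTC) vector.
#' @param site single site name.
#' @param wavelengths strictly increasing wavelengths in nm, within 350-900.
#' @param rrs numeric matrix, one row per timestamp, one column per wavelength,
#'   in sr^-1.
#' @return An object of class `rrs_records`.
#' @export
rrs_records <- function(timestamp, site, wavelengths, rrs) {
  rrs <- as.matrix(rrs)
  stopifnot(inherits(timestamp, "POSIXct"), length(site) == 1L,
            nrow(rrs) == length(timestamp), ncol(rrs) == length(wavelengths))
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (min(wavelengths) < 350 || max(wavelengths) > 900)
    stop("wavelengths outside the 350-900 nm instrument range", call. = FALSE)
  ord <- order(timestamp)
  timestamp <- timestamp[ord]
  rrs <- rrs[ord, , drop = FALSE]
  if (length(timestamp) > 1L &&
      any(diff(as.numeric(timestamp)) < 60))
    stop("record cadence below 1 minute", call. = FALSE)
  structure(list(timestamp = timestamp, site = site,
                 wavelengths = as.numeric(wavelengths), rrs = unname(rrs)),
            class = "rrs_records")
}

#' @export
print.rrs_records <- function(x, ...) {
  cat(sprintf("<rrs_records> site '%s': %d spectra, %d channels (%.1f-%.1f nm)\n",
              x$site, length(x$timestamp), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  if (length(x$timestamp))
    cat(sprintf("  %s .. %s UTC\n", format_utc(min(x$timestamp)),
                format_utc(max(x$timestamp))))
  invisible(x)
}

#' @export
length.rrs_records <- function(x) length(x$timestamp)

#' Construct a weather record table
#'
#' @param timestamp POSIXct (UTC).
#' @param site single site name.
#' @param air_temp,wind_speed,wind_dir,precip,irradiance numeric vectors
#'   (degC, m s^-1, meteorological from-degrees, mm per interval, W m^-2);
#'   any may be omitted and is then NA.
#' @param resolution `"hourly"`, `"daily"`, or NULL to infer from the median
#'   timestamp spacing (<= 2 h means hourly).
#' @return data.frame of class `weather_records`, sorted by timestamp.
#' @export
weather_records <- function(timestamp, site, air_temp = NA_real_,
                            wind_speed = NA_real_, wind_dir = NA_real_,
                            precip = NA_real_, irradiance = NA_real_,
                            resolution = NULL) {
  n <- length(timestamp)
  stopifnot(inherits(timestamp, "POSIXct"), length(site) == 1L)
  d <- data.frame(timestamp = timestamp, site = site,
                  air_temp = rep_len(as.numeric(air_temp), n),
                  wind_speed = rep_len(as.numeric(wind_speed), n),
                  wind_dir = rep_len(as.numeric(wind_dir), n),
                  precip = rep_len(as.numeric(precip), n),
                  irradiance = rep_len(as.numeric(irradiance), n),
                  stringsAsFactors = FALSE)
  d <- d[order(d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  if (any(d$wind_speed < 0, na.rm = TRUE)) stop("wind_speed must be >= 0")
  if (any(d$precip < 0, na.rm = TRUE)) stop("precip must be >= 0")
  if (any(d$wind_dir < 0 | d$wind_dir >= 360, na.rm = TRUE))
    stop("wind_dir must lie in [0, 360)")
  if (is.null(resolution)) resolution <- infer_resolution(d$timestamp)
  d$resolution <- resolution
  class(d) <- c("weather_records", "data.frame")
  d
}

infer_resolution <- function(timestamp) {
  if (length(timestamp) < 2L) return("daily")
  if (stats::median(diff(as.numeric(sort(timestamp)))) <= 2 * 3600) "hourly"
  else "daily"
}

#' Construct a chlorophyll-a observation table
#'
#' @param timestamp POSIXct (UTC).
#' @param site site name (scalar or vector).
#' @param chla concentration mg m^-3; NA where a fatal QC flag applies.
#' @param qc character QC flags, `";"`-joined subset of
#'   `negative_band`, `denominator`, `out_of_range`, `band_missing`;
#'   empty string when clean.
#' @return data.frame of class `chla_obs`, sorted by timestamp within site.
#' @export
chla_obs <- function(timestamp, site, chla, qc = "") {
  n <- length(timestamp)
  d <- data.frame(timestamp = timestamp, site = rep_len(site, n),
                  chla = as.numeric(chla), qc = rep_len(as.character(qc), n),
                  stringsAsFactors = FALSE)
  d <- d[order(d$site, d$timestamp), , drop = FALSE]
  rownames(d) <- NULL
  if (any(d$chla < 0, na.rm = TRUE))
    stop("chla must be >= 0 when present", call. = FALSE)
  class(d) <- c("chla_obs", "data.frame")
  d
}

# ---- readers ---------------------------------------------------------------

#' Read a reflectance table
#'
#' Expects a header row naming a `timestamp` column plus one numeric-named
#' column per wavelength channel (nm). Records are sorted by timestamp.
#'
#' @param path CSV file path.
#' @param site site name to attach.
#' @return An [rrs_records] object.
#' @export
read_rrs_table <- function(path, site) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"timestamp" %in% names(d))
    stop("format error: no 'timestamp' column in ", path, call. = FALSE)
  wl_cols <- setdiff(names(d), "timestamp")
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl))
    stop("format error: non-numeric wavelength column name(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "), call. = FALSE)
  if (any(diff(wl) <= 0))
    stop("format error: wavelength header not strictly increasing", call. = FALSE)
  ts <- parse_utc(d$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp '%s' at line %d of %s",
                 d$timestamp[bad], bad + 1L, path), call. = FALSE)
  }
  rrs_records(ts, site, wl, as.matrix(d[, wl_cols, drop = FALSE]))
}

#' Read a weather table
#'
#' The header must name `timestamp`; any subset of `air_temp`, `wind_speed`,
#' `wind_dir`, `precip`, `irradiance` may follow. Missing columns become NA
#' (some stations only report daily temperature). Resolution is inferred from
#' the median timestamp spacing.
#'
#' @inheritParams read_rrs_table
#' @return data.frame of class `weather_records`.
#' @export
read_weather_table <- function(path, site) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("format error: ", conditionMessage(e),
                                         call. = FALSE))
  if (nrow(d) == 0L) stop("format error: empty weather file ", path, call. = FALSE)
  if (!"timestamp" %in% names(d))
    stop("format error: no 'timestamp' column in ", path, call. = FALSE)
  ts <- parse_utc(d$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable timestamp '%s' at line %d of %s",
                 d$timestamp[bad], bad + 1L, path), call. = FALSE)
  }
  get <- function(col) if (col %in% names(d)) as.numeric(d[[col]]) else NA_real_
  weather_records(ts, site,
                  air_temp = get("air_temp"), wind_speed = get("wind_speed"),
                  wind_dir = get("wind_dir"), precip = get("precip"),
                  irradiance = get("irradiance"))
}

#' Read a chlorophyll-a observation table
#' @param path CSV written by [write_table()] for a `chla_obs` object.
#' @return data.frame of class `chla_obs`.
#' @export
read_chla_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(qc = "character"))
  ts <- parse_utc(d$timestamp)
  if (anyNA(ts)) stop("unparseable timestamp in ", path, call. = FALSE)
  chla_obs(ts, d$site, d$chla, d$qc)
}

# ---- writer ----------------------------------------------------------------

#' Write a record sequence as a delimited table
#'
#' Generic writer for the package's record containers; `read_*` on the written
#' file reproduces the records field-for-field.
#'
#' @param records a non-empty homogeneous record object ([rrs_records],
#'   [weather_records], [chla_obs], or a plain data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) UseMethod("write_table")

#' @export
write_table.default <- function(records, path) {
  stop("usage error: cannot write records of class ",
       paste(class(records), collapse = "/"),
       " (heterogeneous or unknown record type)", call. = FALSE)
}

#' @export
write_table.rrs_records <- function(records, path) {
  if (length(records$timestamp) == 0L)
    stop("usage error: empty record sequence", call. = FALSE)
  d <- as.data.frame(records$rrs)
  names(d) <- format(records$wavelengths, trim = TRUE, digits = 15)
  d <- cbind(timestamp = format_utc(records$timestamp), d)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.weather_records <- function(records, path) {
  if (nrow(records) == 0L)
    stop("usage error: empty record sequence", call. = FALSE)
  d <- as.data.frame(records)
  d$timestamp <- format_utc(d$timestamp)
  d <- d[, c("timestamp", "air_temp", "wind_speed", "wind_dir", "precip",
             "irradiance")]
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
write_table.chla_obs <- function(records, path) {
  if (nrow(records) == 0L)
    stop("usage error: empty record sequence", call. = FALSE)
  d <- as.data.frame(records)
  d$timestamp <- format_utc(d$timestamp)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
write_table.data.frame <- function(records, path) {
  if (nrow(records) == 0L)
    stop("usage error: empty record sequence", call. = FALSE)
  d <- records
  for (j in seq_along(d)) if (inherits(d[[j]], "POSIXct"))
    d[[j]] <- format_utc(d[[j]])
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
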