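#' Coefficients of the turbid-water red/NIR band-ratio retrieval
#'
#' The retrieval converts remote-sensing reflectance at 672, 704 and 776 nm to
#' a chlorophyll-a concentration via
#' \deqn{Chl = \frac{(R_{704}/R_{672})(a_w(704) + b_b) - a_w(672) - b_b^p}{a^*}}
#' with particulate backscattering estimated from the 776 nm band as
#' \eqn{b_b = b_1 R_{776} / (b_2 - b_3 R_{776})}. The defaults follow the
#' semi-analytical turbid/eutrophic-water algorithm family this model belongs
#' to; all constants are exposed so site-specific calibrations can replace
#' them. Package tests rely only on forward/inverse consistency, never on the
#' absolute default values.
#'
#' @param aw672,aw704 pure-water absorption at 672 and 704 nm (m^-1).
#' @param p backscatter exponent (dimensionless).
#' @param a_star chlorophyll-a specific absorption (m^2 mg^-1).
#' @param b1,b2,b3 backscatter-from-Rrs776 coefficients
#'   (m^-1 sr, sr^-1, dimensionless).
#' @return list of class `retrieval_coefficients`.
#' @export
retrieval_coefficients <- function(aw672 = 0.40, aw704 = 0.70, p = 1.06,
                                   a_star = 0.016, b1 = 1.61, b2 = 0.082,
                                   b3 = 0.60) {
  co <- list(aw672 = aw672, aw704 = aw704, p = p, a_star = a_star,
             b1 = b1, b2 = b2, b3 = b3)
  if (any(unlist(co[c("aw672", "aw704", "a_star", "b1", "b2", "p")]) <= 0))
    stop("aw672, aw704, a_star, b1, b2 and p must all be > 0", call. = FALSE)
  structure(co, class = "retrieval_coefficients")
}

#' Extract a band from a spectrum by linear interpolation
#'
#' At the instrument's ~4.6 nm channel spacing, nearest-channel lookup can be
#' off by up to 2.3 nm; linear interpolation between the two bracketing
#' channels is used instead. An exact channel hit returns the stored value.
#'
#' @param rec an [rrs_records] object.
#' @param target_nm wavelength to extract, nm.
#' @return numeric vector of reflectance (sr^-1), one value per spectrum;
#'   NA with attribute when outside the recorded range (flagged upstream as
#'   `band_missing`).
#' @export
extract_band <- function(rec, target_nm) {
  wl <- rec$wavelengths
  if (target_nm < wl[1] || target_nm > wl[length(wl)])
    return(rep(NA_real_, nrow(rec$rrs)))
  hit <- match(target_nm, wl)
  if (!is.na(hit)) return(rec$rrs[, hit])
  hi <- which(wl > target_nm)[1]
  lo <- hi - 1L
  f <- (target_nm - wl[lo]) / (wl[hi] - wl[lo])
  (1 - f) * rec$rrs[, lo] + f * rec$rrs[, hi]
}

#' Particulate backscattering from reflectance at 776 nm
#'
#' @param rrs776 reflectance at 776 nm (sr^-1), vectorized.
#' @param coef [retrieval_coefficients].
#' @return backscattering coefficient b_b (m^-1); NA where the denominator
#'   `b2 - b3 * rrs776` is not positive (the algorithm's pole).
#' @export
backscatter_776 <- function(rrs776, coef = retrieval_coefficients()) {
  den <- coef$b2 - coef$b3 * rrs776
  bb <- ifelse(!is.na(rrs776) & rrs776 >= 0 & den > 0,
               coef$b1 * rrs776 / den, NA_real_)
  bb
}

#' Retrieve chlorophyll-a from reflectance spectra
#'
#' Applies the band-ratio model to every spectrum in `rec`. QC flags:
#' `band_missing` (a required band outside the spectral range),
#' `negative_band` (a required band negative — no value reported),
#' `denominator` (Rrs672 <= 0 or backscatter pole), `out_of_range` (negative
#' retrieval, clipped to 0 but flagged rather than discarded so time-series
#' continuity is preserved).
#'
#' @param rec an [rrs_records] object.
#' @param coef [retrieval_coefficients].
#' @return data.frame of class `chla_obs` with one row per spectrum.
#' @export
retrieve_chla <- function(rec, coef = retrieval_coefficients()) {
  r672 <- extract_band(rec, 672)
  r704 <- extract_band(rec, 704)
  r776 <- extract_band(rec, 776)
  n <- length(rec$timestamp)
  chla <- rep(NA_real_, n)
  qc <- character(n)
  add_flag <- function(qc, mask, flag) {
    qc[mask] <- ifelse(qc[mask] == "", flag, paste(qc[mask], flag, sep = ";"))
    qc
  }
  missing_band <- is.na(r672) | is.na(r704) | is.na(r776)
  qc <- add_flag(qc, missing_band, "band_missing")
  neg <- !missing_band & (r672 < 0 | r704 < 0 | r776 < 0)
  qc <- add_flag(qc, neg, "negative_band")
  bb <- backscatter_776(r776, coef)
  den_bad <- !missing_band & !neg & (r672 <= 0 | is.na(bb))
  qc <- add_flag(qc, den_bad, "denominator")
  ok <- !missing_band & !neg & !den_bad
  val <- ((r704[ok] / r672[ok]) * (coef$aw704 + bb[ok]) - coef$aw672 -
            bb[ok]^coef$p) / coef$a_star
  below <- val < 0
  chla[ok] <- pmax(val, 0)
  oor <- rep(FALSE, n); oor[which(ok)[below]] <- TRUE
  qc <- add_flag(qc, oor, "out_of_range")
  chla_obs(rec$timestamp, rec$site, chla, qc)
}

#' Forward model: reflectance triple from a chlorophyll-a concentration
#'
#' Algebraic inverse of [retrieve_chla()]: given a concentration, a
#' backscattering coefficient and a reference red-band reflectance, returns
#' the (672, 704, 776) nm reflectances on which the retrieval reproduces the
#' concentration exactly. Used by the synthetic scenario generator and the
#' round-trip tests.
#'
#' @param chla concentration mg m^-3 (>= 0), vectorized.
#' @param bb backscattering coefficient m^-1 (>= 0).
#' @param rrs672 reference reflectance at 672 nm (> 0), sr^-1.
#' @param coef [retrieval_coefficients].
#' @return data.frame with columns `rrs672`, `rrs704`, `rrs776`.
#' @export
forward_rrs <- function(chla, bb = 0.35, rrs672 = 0.010,
                        coef = retrieval_coefficients()) {
  stopifnot(all(chla >= 0), all(bb >= 0), all(rrs672 > 0))
  n <- max(length(chla), length(bb), length(rrs672))
  chla <- rep_len(chla, n); bb <- rep_len(bb, n); rrs672 <- rep_len(rrs672, n)
  rrs704 <- rrs672 * (coef$a_star * chla + coef$aw672 + bb^coef$p) /
    (coef$aw704 + bb)
  rrs776 <- coef$b2 * bb / (coef$b1 + coef$b3 * bb)
  data.frame(rrs672 = rrs672, rrs704 = rrs704, rrs776 = rrs776)
}

#' Summarize reflectance spectra over a deployment period
#'
#' Mean and 5th/95th percentile spectra across daily-averaged spectra, the
#' standard spectral-envelope summary for a fixed-station deployment.
#' Percentiles use the linear-interpolation definition
#' (`stats::quantile(type = 7)`).
#'
#' @param rec an [rrs_records] object (all spectra on one wavelength grid).
#' @return list of class `spectral_summary` with `wavelengths`, `mean_rrs`,
#'   `p5_rrs`, `p95_rrs`, `n_days`.
#' @export
summarize_rrs <- function(rec) {
  stopifnot(inherits(rec, "rrs_records"))
  if (length(rec$timestamp) < 1L) stop("usage error: no spectra", call. = FALSE)
  day <- as.Date(rec$timestamp, tz = "UTC")
  daily <- rowsum(rec$rrs, group = as.character(day)) /
    as.vector(table(as.character(day)))
  s <- list(wavelengths = rec$wavelengths,
            mean_rrs = colMeans(daily),
            p5_rrs = apply(daily, 2, stats::quantile, probs = 0.05,
                           names = FALSE),
            p95_rrs = apply(daily, 2, stats::quantile, probs = 0.95,
                            names = FALSE),
            n_days = nrow(daily))
  if (any(s$p5_rrs > s$p95_rrs + 1e-12))
    stop("internal error: p5 > p95")  # invariant
  structure(s, class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d channels, %d days; mean Rrs %.4g-%.4g sr^-1\n",
              length(x$wavelengths), x$n_days, min(x$mean_rrs), max(x$mean_rrs)))
  invisible(x)
}

#' Plausibility-bound QC filter for retrieved chlorophyll-a
#'
#' Values outside `bounds` gain the `out_of_range` flag and have their value
#' withheld from downstream aggregation (set NA). Nothing is silently
#' dropped: every exclusion is reported via a message and remains in the
#' table with its flag.
#'
#' @param obs `chla_obs` table.
#' @param bounds length-2 numeric, min < max, mg m^-3. The default spans the
#'   hypereutrophic range reported for the study systems (4 to >400 mg m^-3)
#'   with headroom.
#' @return `chla_obs` table; excluded rows carry `out_of_range` and NA chla.
#' @export
qc_filter <- function(obs, bounds = c(0, 1000)) {
  stopifnot(inherits(obs, "chla_obs"), length(bounds) == 2L,
            bounds[1] < bounds[2])
  bad <- !is.na(obs$chla) & (obs$chla < bounds[1] | obs$chla > bounds[2])
  if (any(bad)) {
    message(sum(bad), " observation(s) outside [", bounds[1], ", ", bounds[2],
            "] mg m^-3 flagged out_of_range")
    obs$qc[bad] <- ifelse(obs$qc[bad] == "", "out_of_range",
                          paste(obs$qc[bad], "out_of_range", sep = ";"))
    obs$chla[bad] <- NA_real_
  }
  obs
}
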