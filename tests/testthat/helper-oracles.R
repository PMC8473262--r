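# Independent brute-force oracles and small fixture builders.

# naive NPMR: double loop over queries and training points
naive_npmr_estimate <- function(x_train, y_train, tol, x_query,
                                exclude = NULL, min_nb = 0) {
  x_train <- as.matrix(x_train); x_query <- as.matrix(x_query)
  sapply(seq_len(nrow(x_query)), function(q) {
    w <- numeric(nrow(x_train))
    for (j in seq_len(nrow(x_train))) {
      wj <- 1
      for (k in seq_len(ncol(x_train)))
        wj <- wj * exp(-0.5 * ((x_query[q, k] - x_train[j, k]) / tol[k])^2)
      w[j] <- wj
    }
    if (!is.null(exclude)) w[exclude] <- 0
    if (sum(w) < min_nb || sum(w) == 0) NA_real_ else sum(w * y_train) / sum(w)
  })
}

naive_neighborhood <- function(x_train, tol) {
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    wj <- 1
    for (k in seq_len(ncol(x_train)))
      wj <- wj * exp(-0.5 * ((x_train[i, k] - x_train[j, k]) / tol[k])^2)
    out[i] <- out[i] + wj
  }
  out
}

naive_loo_xr2 <- function(x_train, y_train, tol, min_nb = 0) {
  est <- sapply(seq_len(nrow(as.matrix(x_train))), function(i)
    naive_npmr_estimate(x_train, y_train, tol, as.matrix(x_train)[i, , drop = FALSE],
                        exclude = i, min_nb = min_nb))
  ok <- !is.na(est)
  1 - sum((y_train[ok] - est[ok])^2) / sum((y_train[ok] - mean(y_train[ok]))^2)
}

# brute-force flexible-beta agglomeration (same semantics, independent code
# path: merges tracked by explicit membership lists)
brute_flexible_beta <- function(d, beta = -0.25) {
  d <- as.matrix(d)
  n <- nrow(d)
  alpha <- (1 - beta) / 2
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  dm <- d
  heights <- numeric(n - 1)
  merges <- matrix(0L, n - 1, 2)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    bi <- bj <- NA; bd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (dm[i, j] < bd - 1e-15) { bd <- dm[i, j]; bi <- i; bj <- j }
    merges[step, ] <- sort(c(ids[bi], ids[bj]))
    heights[step] <- bd
    newrow <- sapply(seq_len(m), function(k)
      if (k %in% c(bi, bj)) NA else alpha * (dm[k, bi] + dm[k, bj]) +
        beta * dm[bi, bj])
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[bi] <- step
    dm[bi, ] <- dm[, bi] <- newrow
    dm[bi, bi] <- 0
    clusters <- clusters[-bj]; ids <- ids[-bj]
    dm <- dm[-bj, -bj, drop = FALSE]
  }
  list(merge = merges, height = heights)
}

# brute-force maximum short-window temperature decline
brute_max_decline <- function(date, temp, window) {
  best <- 0
  for (i in seq_along(date)) for (j in seq_along(date)) {
    lag <- as.numeric(date[j] - date[i])
    if (lag > 0 && lag <= window && !is.na(temp[i]) && !is.na(temp[j]))
      best <- max(best, temp[i] - temp[j])
  }
  best
}

# planted two-shape relativized diel profiles with additive noise
planted_profiles <- function(n, noise_sd = 0.05, seed = 1) {
  set.seed(seed)
  concave <- c(1, 0.85, 0.7, 0.6, 0.6, 0.7, 0.85, 1)
  convex <- c(0.6, 0.75, 0.9, 1, 1, 0.9, 0.75, 0.6)
  lab <- rep(c("concave", "convex"), length.out = n)
  m <- t(sapply(lab, function(l)
    pmax(0, (if (l == "concave") concave else convex) + rnorm(8, 0, noise_sd))))
  rownames(m) <- paste0("day", seq_len(n))
  list(m = m, labels = lab)
}

# 3-row reflectance fixture on a small grid
toy_rrs <- function(nrec = 3, wl = seq(660, 790, by = 5), seed = 1,
                    site = "toy") {
  set.seed(seed)
  ts <- as.POSIXct("2019-07-01 09:00:00", tz = "UTC") + (seq_len(nrec) - 1) * 900
  rrs_records(ts, site, wl,
              matrix(runif(nrec * length(wl), 0.004, 0.02), nrec))
}

# hourly weather covering `days` days, deterministic
toy_weather <- function(days = 10, site = "toy",
                        start = as.Date("2019-07-01")) {
  ts <- as.POSIXct(paste(start), tz = "UTC") + seq(0, days * 24 - 1) * 3600
  h <- as.integer(format(ts, "%H"))
  weather_records(ts, site,
                  air_temp = 20 + 5 * cos(2 * pi * (h - 14) / 24),
                  wind_speed = 3 + (seq_along(ts) %% 5) / 2,
                  wind_dir = (200 + seq_along(ts)) %% 360,
                  precip = ifelse(seq_along(ts) %% 30 == 0, 2, 0),
                  irradiance = 800 * pmax(0, sin(pi * (h - 6) / 12)))
}
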