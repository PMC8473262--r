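#' @title Pipeline driver
#' @description End-to-end orchestration: (synthetic or file) inputs ->
#'   chlorophyll retrieval -> aggregation and features -> diel clustering ->
#'   driver classification -> NPMR. Every stage writes its tables under the
#'   configured output directory and appends to a log; the run is
#'   deterministic given the config and seed.
#' @name lakechla-pipeline
NULL

#' Read a pipeline configuration
#'
#' @param config a YAML file path or a list. Recognized top-level keys:
#'   `out_dir` (required), `seed`, and either `scenario` (options passed to
#'   [scenario_config()]) or `inputs` (`rrs` and `weather`: named maps
#'   site -> CSV path); optional `retrieval` (coefficient overrides),
#'   `qc_bounds`, `cluster` (`k`, `beta`), `drivers` (`threshold`,
#'   `predictors`), `npmr` (`response`, `candidates`, `grid`, `min_gain`,
#'   `n_perm`).
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("configuration error: config file not found: ",
                                   config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  missing_keys <- setdiff("out_dir", names(config))
  if (is.null(config$scenario) && is.null(config$inputs))
    missing_keys <- c(missing_keys, "scenario|inputs")
  if (length(missing_keys))
    stop("configuration error: missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  config
}

.scenario_from_config <- function(config) {
  sc <- config$scenario
  if (isTRUE(sc) || is.null(sc) || (is.list(sc) && !length(sc)))
    sc <- list()
  args <- list()
  for (f in c("start", "end")) if (!is.null(sc[[f]]))
    args[[f]] <- as.Date(sc[[f]])
  for (f in c("cadence_minutes", "noise_cv", "post_storm_step",
              "rrs_noise_cv", "daily_sites"))
    if (!is.null(sc[[f]])) args[[f]] <- sc[[f]]
  if (!is.null(sc$heatwave)) {
    args$heatwave <- sc$heatwave
    args$heatwave$start <- as.Date(args$heatwave$start)
  }
  if (!is.null(sc$storm)) {
    args$storm <- sc$storm
    args$storm$date <- as.Date(args$storm$date)
  }
  args$seed <- if (!is.null(sc$seed)) sc$seed else config$seed
  do.call(scenario_config, args)
}

#' Run the analysis pipeline
#'
#' @param config path to a YAML config or a config list
#'   (see [read_pipeline_config()]).
#' @param stages stages to execute, in order; prerequisites not executed in
#'   this call are loaded from the tables a previous run left in `out_dir`.
#' @return invisibly, a list of in-memory stage results; tables and
#'   `pipeline.log` are written under `out_dir`.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "retrieve", "features",
                                    "cluster", "drivers", "npmr")) {
  cfg <- read_pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "pipeline.log")
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  res <- list()

  sites <- NULL; rrs_files <- NULL; weather_files <- NULL
  if (!is.null(cfg$scenario)) {
    scfg <- .scenario_from_config(cfg)
    sites <- scfg$sites$name
    if ("simulate" %in% stages) {
      log("simulate: generating scenario (seed ", scfg$seed, ")")
      res$scenario <- generate_scenario(scfg, file.path(out, "scenario"))
    }
    rrs_files <- stats::setNames(
      file.path(out, "scenario", paste0("rrs_", sites, ".csv")), sites)
    weather_files <- stats::setNames(
      file.path(out, "scenario", paste0("weather_", sites, ".csv")), sites)
  } else {
    rrs_files <- unlist(cfg$inputs$rrs)
    weather_files <- unlist(cfg$inputs$weather)
    sites <- union(names(rrs_files), names(weather_files))
  }
  has_weather <- length(weather_files) > 0 && all(file.exists(weather_files))

  if ("retrieve" %in% stages) {
    co <- do.call(retrieval_coefficients,
                  if (is.null(cfg$retrieval)) list() else cfg$retrieval)
    bounds <- if (is.null(cfg$qc_bounds)) c(0, 1000) else
      as.numeric(cfg$qc_bounds)
    obs <- list()
    for (s in names(rrs_files)) {
      rec <- read_rrs_table(rrs_files[[s]], s)
      o <- qc_filter(retrieve_chla(rec, co), bounds)
      n_flag <- sum(o$qc != "")
      log("retrieve: ", s, ": ", nrow(o), " spectra, ", n_flag, " flagged")
      obs[[s]] <- o
      summ <- summarize_rrs(rec)
      write_table(data.frame(wavelength = summ$wavelengths,
                             mean_rrs = summ$mean_rrs, p5_rrs = summ$p5_rrs,
                             p95_rrs = summ$p95_rrs),
                  file.path(out, paste0("rrs_summary_", s, ".csv")))
    }
    all_obs <- do.call(rbind, lapply(obs, as.data.frame))
    res$chla <- chla_obs(all_obs$timestamp, all_obs$site, all_obs$chla,
                         all_obs$qc)
    write_table(res$chla, file.path(out, "chla_obs.csv"))
  }

  need_chla <- function() {
    if (!is.null(res$chla)) return(res$chla)
    f <- file.path(out, "chla_obs.csv")
    if (!file.exists(f))
      stop("configuration error: retrieve stage output missing (", f, ")",
           call. = FALSE)
    read_chla_table(f)
  }

  if ("features" %in% stages) {
    chla <- need_chla()
    hourly <- aggregate_series(chla, "hourly")
    daily <- aggregate_series(chla, "daily")
    res$profiles <- diel_profiles(hourly)
    if (length(unique(res$profiles$site)) >= 2L)
      res$profiles <- common_days(res$profiles)
    write_table(as.data.frame(res$profiles),
                file.path(out, "diel_profiles.csv"))
    log("features: ", nrow(res$profiles), " complete common site-days")
    if (has_weather) {
      feats <- list()
      for (s in names(weather_files)) {
        w <- read_weather_table(weather_files[[s]], s)
        feats[[s]] <- antecedent_features(w, daily)
      }
      res$features <- do.call(rbind, lapply(feats, as.data.frame))
      class(res$features) <- c("daily_features", "data.frame")
      write_table(as.data.frame(res$features),
                  file.path(out, "daily_features.csv"))
      ev <- detect_max_decline(data.frame(site = res$features$site,
                                          date = res$features$date,
                                          temp = res$features$temp))
      if (!is.null(ev)) {
        res$events <- ev
        write_table(as.data.frame(ev), file.path(out, "events.csv"))
        log("features: max temperature decline ",
            sprintf("%.1f", max(ev$decline)), " degC at ",
            ev$site[which.max(ev$decline)])
      }
    } else {
      log("features: no weather inputs; driver/NPMR stages will be skipped")
    }
  }

  need_profiles <- function() {
    if (!is.null(res$profiles)) return(res$profiles)
    f <- file.path(out, "diel_profiles.csv")
    if (!file.exists(f))
      stop("configuration error: features stage output missing", call. = FALSE)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    d$date <- as.Date(d$date)
    class(d) <- c("diel_profiles", "data.frame")
    d
  }
  need_features <- function() {
    if (!is.null(res$features)) return(res$features)
    f <- file.path(out, "daily_features.csv")
    if (!file.exists(f)) return(NULL)
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    d$date <- as.Date(d$date)
    class(d) <- c("daily_features", "data.frame")
    d
  }

  if ("cluster" %in% stages) {
    prof <- need_profiles()
    k <- if (is.null(cfg$cluster$k)) 5L else cfg$cluster$k
    beta <- if (is.null(cfg$cluster$beta)) -0.25 else cfg$cluster$beta
    k <- min(k, nrow(prof))
    dmat <- sorensen_matrix(prof)
    tree <- flexible_beta_cluster(dmat, beta = beta)
    res$assignment <- cut_to_groups(tree, k)
    write_table(as.data.frame(res$assignment),
                file.path(out, "cluster_assignment.csv"))
    write_table(cluster_profiles(res$assignment, prof),
                file.path(out, "cluster_profiles.csv"))
    feats <- need_features()
    if (!is.null(feats))
      write_table(cluster_covariate_summary(res$assignment, feats),
                  file.path(out, "cluster_covariates.csv"))
    log("cluster: k = ", k, ", groups ",
        paste(sort(unique(res$assignment$group)), collapse = ", "))
  }

  need_assignment <- function() {
    if (!is.null(res$assignment)) return(res$assignment)
    f <- file.path(out, "cluster_assignment.csv")
    if (!file.exists(f))
      stop("configuration error: cluster stage output missing", call. = FALSE)
    utils::read.csv(f, stringsAsFactors = FALSE)
  }

  if ("drivers" %in% stages) {
    feats <- need_features()
    if (is.null(feats)) {
      warning("drivers stage skipped: no weather-derived features",
              call. = FALSE)
      log("drivers: skipped (no weather)")
    } else {
      asg <- need_assignment()
      key <- paste(feats$date, feats$site)
      idx <- match(asg$label, key)
      ok <- !is.na(idx)
      pred_names <- if (!is.null(cfg$drivers$predictors))
        cfg$drivers$predictors else
          c("irradiance", "temp", "wind", "rain")
      fdat <- feats[idx[ok], pred_names, drop = FALSE]
      fdat$site <- factor(feats$site[idx[ok]])
      thr <- if (is.null(cfg$drivers$threshold)) 0.6 else
        cfg$drivers$threshold
      kept <- screen_collinear(fdat, threshold = thr)
      log("drivers: retained predictors ", paste(kept, collapse = ", "))
      model <- fit_multinomial(fdat[, kept, drop = FALSE],
                               asg$group[ok])
      res$driver_model <- model
      wt <- wald_tests(model)
      write_table(wt, file.path(out, "driver_coefficients.csv"))
      ct <- confusion_table(model)
      res$confusion <- ct
      pc <- as.data.frame(as.table(ct$percent))
      names(pc) <- c("predicted", "true", "percent")
      write_table(pc, file.path(out, "confusion_table.csv"))
      log("drivers: mean diagonal percent correct ",
          sprintf("%.1f", mean(diag(ct$percent))))
    }
  }

  if ("npmr" %in% stages) {
    feats <- need_features()
    if (is.null(feats)) {
      warning("npmr stage skipped: no weather-derived features", call. = FALSE)
      log("npmr: skipped (no weather)")
    } else {
      ncfg <- cfg$npmr
      response <- if (is.null(ncfg$response)) "chla_daily" else ncfg$response
      candidates <- if (is.null(ncfg$candidates))
        c("doy", "temp", "temp7", "wind", "rain7") else ncfg$candidates
      grid <- if (is.null(ncfg$grid)) .default_tol_grid else
        as.numeric(ncfg$grid)
      min_gain <- if (is.null(ncfg$min_gain)) 0.02 else ncfg$min_gain
      n_perm <- if (is.null(ncfg$n_perm)) 199L else as.integer(ncfg$n_perm)
      rows <- list()
      for (s in unique(feats$site)) {
        d <- feats[feats$site == s, , drop = FALSE]
        if (sum(stats::complete.cases(d[, c(response, candidates)])) < 10) {
          log("npmr: ", s, ": too few complete days, skipped")
          next
        }
        search <- free_search(d, response, candidates, grid = grid,
                              min_gain = min_gain)
        if (is.null(search$best)) {
          log("npmr: ", s, ": ", search$diagnostic)
          next
        }
        m <- search$best
        sens <- npmr_sensitivity(m)
        pt <- npmr_permutation_test(m, n_perm = n_perm, seed = cfg$seed)
        res$npmr[[s]] <- list(search = search, sensitivity = sens,
                              permutation = pt)
        rows[[s]] <- data.frame(
          site = s, xr2 = m$xr2, avg_size = m$avg_neighborhood,
          predictors = paste(m$predictors, collapse = "+"),
          tolerances = paste(sprintf("%.4g", m$tolerances), collapse = "+"),
          sensitivities = paste(sprintf("%.3g", sens$sensitivity),
                                collapse = "+"),
          p = pt$p)
        log("npmr: ", s, ": xR2 ", sprintf("%.3f", m$xr2), " with ",
            paste(m$predictors, collapse = " + "), ", p = ",
            sprintf("%.3f", pt$p))
      }
      if (length(rows))
        write_table(do.call(rbind, rows), file.path(out, "npmr_models.csv"))
    }
  }
  invisible(res)
}
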