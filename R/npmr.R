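#' @title Nonparametric Multiplicative Regression (NPMR)
#' @description Local-mean kernel regression in which each predictor
#'   contributes a Gaussian weight and the weights multiply, so predictors
#'   interact without fixed coefficients. Fit is summarized by the
#'   leave-one-out cross-validated R-squared (xR2, which can be negative),
#'   effective sample size by the average neighborhood size N* (the mean sum
#'   of kernel weights a point receives), variable importance by the
#'   sensitivity to +/-5%-of-range predictor nudges, and significance by a
#'   response-permutation test. Model selection is a stepwise free search
#'   over predictors and per-predictor tolerances (kernel SDs in predictor
#'   units).
#' @name lakechla-npmr
NULL

.default_tol_grid <- c(0.025, 0.05, 0.10, 0.15, 0.20, 0.30, 0.45, 0.65, 1.0)

#' Construct (and evaluate) an NPMR model
#'
#' The weight point j gives point i is
#' \deqn{w_{ij} = \prod_k \exp\left(-\tfrac12 ((x_{ik} - x_{jk})/t_k)^2\right)}
#' and the estimate at a point is the weighted mean of the other points'
#' responses. Points whose total leave-one-out weight falls below
#' `min_neighborhood` get no estimate and are excluded from the fit sums.
#'
#' @param data data.frame of training data.
#' @param response response column name.
#' @param predictors predictor column names.
#' @param tolerances per-predictor kernel SDs, in predictor units.
#' @param min_neighborhood minimum total weight for a valid estimate;
#'   default `0.05 * n`. Pass 0 to disable (useful for tiny worked examples
#'   whose endpoint neighborhoods are necessarily small).
#' @return list of class `npmr_model` with the training data, tolerances,
#'   `xr2`, `avg_neighborhood`, `n`, `n_estimated`.
#' @export
npmr_model <- function(data, response, predictors, tolerances,
                       min_neighborhood = NULL) {
  stopifnot(length(predictors) == length(tolerances), all(tolerances > 0))
  keep <- stats::complete.cases(data[, c(response, predictors), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 complete observations", call. = FALSE)
  y <- d[[response]]
  if (stats::var(y) == 0) stop("zero response variance", call. = FALSE)
  x <- as.matrix(d[, predictors, drop = FALSE])
  if (is.null(min_neighborhood)) min_neighborhood <- 0.05 * n
  D <- lapply(seq_along(predictors), function(k) outer(x[, k], x[, k], "-")^2)
  m <- structure(list(response = response, predictors = predictors,
                      tolerances = stats::setNames(tolerances, predictors),
                      min_neighborhood = min_neighborhood,
                      x = x, y = y, n = n, D = D),
                 class = "npmr_model")
  loo <- .npmr_loo(m)
  m$xr2 <- loo$xr2
  m$n_estimated <- loo$n_estimated
  m$loo_estimates <- loo$estimates
  nb <- neighborhood_sizes(m)
  m$avg_neighborhood <- nb$mean
  m
}

#' @export
print.npmr_model <- function(x, ...) {
  cat(sprintf("<npmr_model> %s ~ %s; n = %d (%d estimated)\n",
              x$response, paste(x$predictors, collapse = " * "),
              x$n, x$n_estimated))
  cat(sprintf("  xR2 = %.4f, average neighborhood N* = %.2f\n",
              x$xr2, x$avg_neighborhood))
  cat("  tolerances:", paste(sprintf("%s = %.4g", x$predictors, x$tolerances),
                             collapse = ", "), "\n")
  invisible(x)
}

.weight_matrix <- function(D, tolerances) {
  s <- D[[1]] / tolerances[1]^2
  for (k in seq_along(D)[-1]) s <- s + D[[k]] / tolerances[k]^2
  exp(-0.5 * s)
}

.npmr_loo <- function(model, y = model$y) {
  W <- .weight_matrix(model$D, model$tolerances)
  diag(W) <- 0
  .loo_from_W(W, y, model$min_neighborhood)
}

.loo_from_W <- function(W, y, min_nb) {
  sw <- unname(rowSums(W))
  est <- as.vector(W %*% y) / sw
  valid <- sw >= min_nb & sw > 0 & is.finite(est)
  nv <- sum(valid)
  xr2 <- if (nv >= 3L && stats::var(y[valid]) > 0)
    1 - sum((y[valid] - est[valid])^2) / sum((y[valid] - mean(y[valid]))^2)
  else NA_real_
  list(xr2 = xr2, estimates = ifelse(valid, est, NA_real_),
       n_estimated = nv, neighborhood = sw)
}

#' Kernel estimate at query points
#'
#' @param model an `npmr_model`.
#' @param x query points: data.frame/matrix with the model's predictor
#'   columns, or a numeric vector for a single point.
#' @param exclude optional index of one training point to leave out (for
#'   cross-validation).
#' @return numeric vector of estimates; NA where the neighborhood weight sum
#'   falls below `min_neighborhood` (no-estimate) or underflows to zero.
#' @export
npmr_estimate <- function(model, x, exclude = NULL) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, model$predictors))
  x <- as.matrix(as.data.frame(x)[, model$predictors, drop = FALSE])
  keep <- seq_len(model$n)
  if (!is.null(exclude)) keep <- keep[-exclude]
  xt <- model$x[keep, , drop = FALSE]
  yt <- model$y[keep]
  t2 <- model$tolerances^2
  vapply(seq_len(nrow(x)), function(q) {
    s <- 0
    for (k in seq_along(model$predictors))
      s <- s + (x[q, k] - xt[, k])^2 / t2[k]
    w <- exp(-0.5 * s)
    sw <- sum(w)
    if (sw < model$min_neighborhood || sw == 0) NA_real_
    else sum(w * yt) / sw
  }, numeric(1))
}

#' Leave-one-out cross-validated R-squared
#'
#' \eqn{xR^2 = 1 - \sum (y_i - \hat y_{-i})^2 / \sum (y_i - \bar y)^2}, summed
#' over the points that receive an estimate (those meeting
#' `min_neighborhood`); can be negative when cross-validated residuals exceed
#' the response variance.
#'
#' @param model an `npmr_model`.
#' @return xR2 value, with attributes `estimates` (per-point LOO estimates)
#'   and `n_estimated`.
#' @export
loo_xr2 <- function(model) {
  loo <- .npmr_loo(model)
  structure(loo$xr2, estimates = loo$estimates,
            n_estimated = loo$n_estimated)
}

#' Neighborhood sizes
#'
#' `N*_i = sum_{j != i} w_ij`: the effective number of neighbors supporting
#' each point's estimate. The mean is the "average neighborhood size"
#' reported alongside xR2.
#'
#' @param model an `npmr_model`.
#' @return list `sizes` (per point) and `mean`.
#' @export
neighborhood_sizes <- function(model) {
  W <- .weight_matrix(model$D, model$tolerances)
  diag(W) <- 0
  sizes <- unname(rowSums(W))
  list(sizes = sizes, mean = mean(sizes))
}

# optimize tolerances for a fixed predictor subset over grid * range;
# exhaustive over the Cartesian grid when small enough, coordinate-descent
# passes otherwise
.optimize_tolerances <- function(D, y, ranges, grid, min_nb,
                                 coverage = 0.9, max_combos = 2000L) {
  p <- length(D)
  n <- length(y)
  tls <- lapply(seq_len(p), function(k) grid * ranges[k])
  eval_tol <- function(tol) {
    W <- .weight_matrix(D, tol)
    diag(W) <- 0
    loo <- .loo_from_W(W, y, min_nb)
    # a model that silently discards points can fake a high xR2; require
    # estimates for at least `coverage` of the data
    if (loo$n_estimated < ceiling(coverage * n)) NA_real_ else loo$xr2
  }
  if (length(grid)^p <= max_combos) {
    combos <- as.matrix(expand.grid(tls, KEEP.OUT.ATTRS = FALSE))
    xr2s <- apply(combos, 1, eval_tol)
    if (all(is.na(xr2s))) return(NULL)
    best <- which.max(xr2s)
    return(list(tol = combos[best, ], xr2 = xr2s[best]))
  }
  tol <- vapply(tls, stats::median, numeric(1))
  best <- eval_tol(tol)
  for (pass in 1:10) {
    changed <- FALSE
    for (k in seq_len(p)) {
      cand <- vapply(tls[[k]], function(t) {
        tt <- tol; tt[k] <- t; eval_tol(tt)
      }, numeric(1))
      if (all(is.na(cand))) next
      if (max(cand, na.rm = TRUE) > best + 1e-12) {
        tol[k] <- tls[[k]][which.max(cand)]
        best <- max(cand, na.rm = TRUE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (is.na(best)) NULL else list(tol = tol, xr2 = best)
}

#' Fit an NPMR model for a fixed predictor set, optimizing tolerances
#'
#' Grid-optimizes the per-predictor tolerances (fractions of each predictor's
#' observed range) for a given predictor subset, without predictor selection.
#'
#' @inheritParams free_search
#' @param predictors the predictor set to fit.
#' @return an `npmr_model`, or NULL if no tolerance combination achieves the
#'   neighborhood and coverage requirements.
#' @export
npmr_fit <- function(data, response, predictors, grid = .default_tol_grid,
                     min_neighborhood = NULL, coverage = 0.9) {
  keep <- stats::complete.cases(data[, c(response, predictors), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  if (is.null(min_neighborhood)) min_neighborhood <- 0.05 * nrow(d)
  y <- d[[response]]
  D <- lapply(predictors, function(v) outer(d[[v]], d[[v]], "-")^2)
  ranges <- vapply(predictors, function(v) diff(range(d[[v]])), numeric(1))
  if (any(ranges == 0)) stop("constant predictor(s): ",
                             paste(predictors[ranges == 0], collapse = ", "),
                             call. = FALSE)
  opt <- .optimize_tolerances(D, y, ranges, grid, min_neighborhood,
                              coverage = coverage)
  if (is.null(opt)) return(NULL)
  npmr_model(d, response, predictors, opt$tol,
             min_neighborhood = min_neighborhood)
}

#' Stepwise free search over predictors and tolerances
#'
#' Forward selection: at each model size every unused predictor is tried with
#' every tolerance in `grid * range(predictor)` (tolerances of predictors
#' already in the model are re-optimized over the same grid), the highest-xR2
#' model is kept, and the search stops when the xR2 gain falls below
#' `min_gain`. Deterministic given the settings.
#'
#' @param data training data.frame.
#' @param response response column name.
#' @param candidates candidate predictor column names.
#' @param grid tolerance grid as fractions of each predictor's observed
#'   range.
#' @param min_gain minimum absolute xR2 improvement to accept another
#'   predictor (default 0.02 — gains of the order of 1% are treated as
#'   interchangeable rather than improvements).
#' @param max_size cap on model size (default: all candidates).
#' @param min_neighborhood see [npmr_model()].
#' @param coverage minimum fraction of points that must receive an estimate
#'   for a tolerance combination to be admissible (default 0.9); prevents the
#'   search from inflating xR2 by shrinking tolerances until most points are
#'   excluded.
#' @return list of class `npmr_search`: `best` (the selected `npmr_model`),
#'   `by_size` (best model per size), `xr2_by_size`.
#' @export
free_search <- function(data, response, candidates,
                        grid = .default_tol_grid, min_gain = 0.02,
                        max_size = length(candidates),
                        min_neighborhood = NULL, coverage = 0.9) {
  stopifnot(length(candidates) >= 1L, all(grid > 0), all(grid <= 1))
  keep <- stats::complete.cases(data[, c(response, candidates), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  n <- nrow(d)
  if (is.null(min_neighborhood)) min_neighborhood <- 0.05 * n
  y <- d[[response]]
  ranges <- vapply(candidates, function(v) diff(range(d[[v]])), numeric(1))
  usable <- candidates[ranges > 0]
  if (length(usable) < length(candidates))
    warning("dropping constant candidate(s): ",
            paste(setdiff(candidates, usable), collapse = ", "), call. = FALSE)
  Dall <- lapply(usable, function(v) outer(d[[v]], d[[v]], "-")^2)
  names(Dall) <- usable
  rng <- stats::setNames(ranges[match(usable, candidates)], usable)

  current <- character(0); current_xr2 <- -Inf
  by_size <- list(); xr2_by_size <- numeric(0)
  repeat {
    if (length(current) >= min(max_size, length(usable))) break
    best_cand <- NULL
    for (v in setdiff(usable, current)) {
      set <- c(current, v)
      opt <- .optimize_tolerances(Dall[set], y, rng[set], grid,
                                  min_neighborhood, coverage = coverage)
      if (is.null(opt)) next
      if (is.null(best_cand) || opt$xr2 > best_cand$xr2)
        best_cand <- list(set = set, tol = opt$tol, xr2 = opt$xr2)
    }
    if (is.null(best_cand)) break
    size <- length(best_cand$set)
    by_size[[size]] <- npmr_model(d, response, best_cand$set,
                                  best_cand$tol,
                                  min_neighborhood = min_neighborhood)
    xr2_by_size[size] <- best_cand$xr2
    gain <- best_cand$xr2 - ifelse(is.finite(current_xr2), current_xr2, -Inf)
    if (length(current) > 0 && gain < min_gain) {
      by_size[[size]] <- NULL
      xr2_by_size <- xr2_by_size[seq_len(size - 1L)]
      break
    }
    current <- best_cand$set; current_xr2 <- best_cand$xr2
  }
  if (!length(by_size))
    return(structure(list(best = NULL, by_size = list(),
                          xr2_by_size = numeric(0),
                          diagnostic = "no model met the minimum neighborhood"),
                     class = "npmr_search"))
  structure(list(best = by_size[[length(by_size)]], by_size = by_size,
                 xr2_by_size = xr2_by_size, grid = grid,
                 min_gain = min_gain),
            class = "npmr_search")
}

#' @export
print.npmr_search <- function(x, ...) {
  if (is.null(x$best)) {
    cat("<npmr_search> no valid model:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat("<npmr_search> best model per size (xR2):",
      paste(sprintf("%d: %.3f", seq_along(x$xr2_by_size), x$xr2_by_size),
            collapse = "; "), "\n")
  print(x$best)
  invisible(x)
}

#' Sensitivity analysis by +/- 5%-of-range nudges
#'
#' Each predictor in turn is nudged by +/- `nudge` of its observed range at
#' every training point; the mean absolute deviation of the estimate, scaled
#' by the response range and the nudge fraction, is that predictor's
#' sensitivity:
#' \deqn{Q_k = \frac{\sum_i |\hat y(x_i + \delta) - \hat y(x_i)| +
#'   |\hat y(x_i - \delta) - \hat y(x_i)|}{2 n \, \mathrm{range}(y) \,
#'   \mathrm{nudge}}}
#' A linear response fitted at near-interpolation tolerance has sensitivity
#' about 1; a predictor not in the model has sensitivity 0. Points lacking
#' any of the three estimates are skipped symmetrically.
#'
#' @param model an `npmr_model`.
#' @param predictors predictors to report (default: the model's, but any
#'   name can be asked for and returns 0 if absent from the model).
#' @param nudge nudge fraction of each predictor's range (default 0.05).
#' @return data.frame of class `sensitivity_report`: `predictor`,
#'   `sensitivity`, `n_used`.
#' @export
npmr_sensitivity <- function(model, predictors = model$predictors,
                             nudge = 0.05) {
  ry <- diff(range(model$y))
  if (ry == 0) stop("zero response range", call. = FALSE)
  base <- npmr_estimate(model, model$x)
  rows <- lapply(predictors, function(v) {
    if (!v %in% model$predictors)
      return(data.frame(predictor = v, sensitivity = 0, n_used = model$n))
    k <- match(v, model$predictors)
    delta <- nudge * diff(range(model$x[, k]))
    up <- model$x; up[, k] <- up[, k] + delta
    dn <- model$x; dn[, k] <- dn[, k] - delta
    eu <- npmr_estimate(model, up)
    ed <- npmr_estimate(model, dn)
    ok <- !is.na(base) & !is.na(eu) & !is.na(ed)
    q <- if (!any(ok)) NA_real_ else
      sum(abs(eu[ok] - base[ok]) + abs(ed[ok] - base[ok])) /
      (2 * sum(ok) * ry * nudge)
    data.frame(predictor = v, sensitivity = q, n_used = sum(ok))
  })
  out <- do.call(rbind, rows)
  attr(out, "nudge") <- nudge
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Permutation test of an NPMR model
#'
#' The response is permuted `n_perm` times; for each permutation the
#' tolerances of the model's (fixed) predictor set are re-optimized over the
#' tolerance grid and the best xR2 recorded. The p-value is
#' `(1 + #{perm xR2 >= observed}) / (1 + n_perm)`.
#'
#' @param model an `npmr_model`.
#' @param n_perm number of permutations (>= 1; default 199, which resolves
#'   p < 0.05 at minimal cost).
#' @param seed RNG seed for the permutations.
#' @param grid tolerance grid (fractions of range).
#' @param coverage minimum estimated fraction, as in [free_search()].
#' @return list of class `npmr_permutation`: `p`, `observed_xr2`,
#'   `perm_xr2`, `n_perm`.
#' @export
npmr_permutation_test <- function(model, n_perm = 199L, seed = 1L,
                                  grid = .default_tol_grid, coverage = 0.9) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  p <- length(model$predictors)
  ranges <- apply(model$x, 2, function(v) diff(range(v)))
  combos <- as.matrix(expand.grid(lapply(seq_len(p), function(k)
    grid * ranges[k]), KEEP.OUT.ATTRS = FALSE))
  small <- nrow(combos) <= 400L && model$n <= 400L
  Wcache <- if (small) lapply(seq_len(nrow(combos)), function(i) {
    W <- .weight_matrix(model$D, combos[i, ])
    diag(W) <- 0
    W
  })
  need <- ceiling(coverage * model$n)
  best_xr2 <- function(y) {
    if (small) {
      v <- vapply(Wcache, function(W) {
        loo <- .loo_from_W(W, y, model$min_neighborhood)
        if (loo$n_estimated < need) NA_real_ else loo$xr2
      }, numeric(1))
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    } else {
      opt <- .optimize_tolerances(model$D, y, ranges, grid,
                                  model$min_neighborhood, coverage = coverage)
      if (is.null(opt)) NA_real_ else opt$xr2
    }
  }
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    best_xr2(sample(model$y)), numeric(1)))
  pval <- (1 + sum(perm >= model$xr2, na.rm = TRUE)) / (1 + n_perm)
  structure(list(p = pval, observed_xr2 = model$xr2, perm_xr2 = perm,
                 n_perm = n_perm),
            class = "npmr_permutation")
}

#' @export
print.npmr_permutation <- function(x, ...) {
  cat(sprintf("<npmr_permutation> observed xR2 = %.4f, p = %.4f (%d permutations)\n",
              x$observed_xr2, x$p, x$n_perm))
  invisible(x)
}
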