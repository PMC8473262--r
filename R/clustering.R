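#' @title Diel-profile clustering
#' @description Sorensen (quantitative, i.e. Bray-Curtis) distances between
#'   relativized diel profiles, agglomerative clustering with flexible-beta
#'   linkage via the Lance-Williams update, deterministic cutting, and
#'   per-cluster profile and covariate summaries.
#' @name lakechla-clustering
NULL

profile_matrix <- function(profiles) {
  cols <- paste0("h", sprintf("%02d", 9:16))
  stopifnot(all(cols %in% names(profiles)))
  m <- as.matrix(profiles[, cols])
  rownames(m) <- paste(profiles$date, profiles$site)
  m
}

#' Sorensen distance matrix between diel profiles
#'
#' Quantitative Sorensen (Bray-Curtis) distance
#' \eqn{d(x, y) = \sum |x_i - y_i| / \sum (x_i + y_i)}, bounded in `[0, 1]`
#' for nonnegative profiles.
#'
#' @param profiles a complete `diel_profiles` table ([diel_profiles()],
#'   usually after [common_days()]), or a nonnegative numeric matrix with one
#'   profile per row.
#' @return a `dist` object labelled by site-day.
#' @export
sorensen_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else {
    if (!all(profiles$complete))
      stop("all profiles must be complete; run common_days() first",
           call. = FALSE)
    profile_matrix(profiles)
  }
  if (any(m < 0)) stop("profiles must be nonnegative", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero))
    stop("Sorensen distance undefined for all-zero profile row(s): ",
         paste(which(zero), collapse = ", "), call. = FALSE)
  vegan::vegdist(m, method = "bray")
}

#' Agglomerative clustering with flexible-beta linkage
#'
#' Lance-Williams agglomeration
#' \deqn{d(k, i \cup j) = \alpha (d(k,i) + d(k,j)) + \beta d(i,j)}
#' with \eqn{\alpha = (1 - \beta)/2}. At each step the minimum-distance pair
#' is merged, ties broken by the lexicographically smallest pair of current
#' cluster ids. `beta = -0.25` is the conventional "flexible" setting;
#' `beta = 0` reduces to equal-weight average linkage (WPGMA). Merge heights
#' are returned as computed — flexible beta can produce inversions and
#' monotonicity is not asserted.
#'
#' @param d a `dist` object or symmetric matrix of distances.
#' @param beta linkage parameter, `< 1`.
#' @return list of class `merge_tree`: `merge` (hclust-style n-1 x 2 matrix,
#'   negative entries = leaves), `height`, `labels`, `beta`.
#' @export
flexible_beta_cluster <- function(d, beta = -0.25) {
  if (inherits(d, "dist")) {
    labels <- attr(d, "Labels")
    d <- as.matrix(d)
  } else labels <- rownames(d)
  if (!isSymmetric(unname(d)))
    stop("usage error: distance matrix must be symmetric", call. = FALSE)
  if (beta >= 1) stop("beta must be < 1", call. = FALSE)
  n <- nrow(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  alpha <- (1 - beta) / 2
  # active cluster ids: negative = leaf row, positive = merge step
  id <- -seq_len(n)
  active <- seq_len(n)
  merge <- matrix(0L, max(n - 1L, 0L), 2L)
  height <- numeric(max(n - 1L, 0L))
  for (step in seq_len(n - 1L)) {
    # minimum-distance active pair; ties -> smallest (i, j) by current ids
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (a in seq_along(active)[-length(active)]) {
      i <- active[a]
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        if (d[i, j] < bd - 1e-15) {
          bd <- d[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bd
    # Lance-Williams update written into slot i; retire slot j
    for (k in setdiff(active, c(i, j)))
      d[i, k] <- d[k, i] <- alpha * (d[k, i] + d[k, j]) + beta * d[i, j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height, labels = labels,
                 beta = beta, n = n),
            class = "merge_tree")
}

#' @export
print.merge_tree <- function(x, ...) {
  cat(sprintf("<merge_tree> %d leaves, flexible beta = %.3g, heights %.3g-%.3g\n",
              x$n, x$beta, min(x$height), max(x$height)))
  invisible(x)
}

#' Cut a merge tree into k groups
#'
#' Undoes the last `k - 1` merges, then numbers each end group by the 1-based
#' original row index of its first member (the first-member numbering rule,
#' which yields labels such as 48, 42, 13, 1, 6 rather than 1..k).
#'
#' @param tree a `merge_tree`.
#' @param k number of groups, `1 <= k <= n`.
#' @return data.frame of class `cluster_assignment`: `row`, `label`
#'   (site-day), `group` (first-member group number).
#' @export
cut_to_groups <- function(tree, k) {
  n <- tree$n
  if (k < 1 || k > n) stop("usage error: k must lie in [1, n]", call. = FALSE)
  # membership after applying the first n - k merges
  if (n - k >= 1) {
    merged <- vector("list", n - 1L)
    get_members <- function(cid) if (cid < 0) -cid else merged[[cid]]
    for (step in seq_len(n - k)) {
      a <- tree$merge[step, 1]; b <- tree$merge[step, 2]
      merged[[step]] <- c(get_members(a), get_members(b))
    }
    # leaves belonging to clusters formed at steps that were later merged
    # again (within the first n-k) are superseded; assign by last formation
    grp <- seq_len(n)
    for (step in seq_len(n - k)) grp[merged[[step]]] <- n + step
  } else grp <- seq_len(n)
  ugrp <- unique(grp)
  out <- data.frame(row = seq_len(n),
                    label = tree$labels,
                    stringsAsFactors = FALSE)
  # group number = smallest original row index among members (the first item
  # assigned to the group in row order)
  gnum <- vapply(ugrp, function(g) min(which(grp == g)), integer(1))
  out$group <- gnum[match(grp, ugrp)]
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Per-cluster mean diel profile with standard errors
#'
#' @param assignment a `cluster_assignment` from [cut_to_groups()].
#' @param profiles the `diel_profiles` table that was clustered (same row
#'   order).
#' @return long data.frame: `group`, `hour` (9-16), `mean`, `se`
#'   (`sd/sqrt(n)`; 0 for singleton clusters), `n`.
#' @export
cluster_profiles <- function(assignment, profiles) {
  m <- profile_matrix(profiles)
  stopifnot(nrow(m) == nrow(assignment))
  out <- lapply(sort(unique(assignment$group)), function(g) {
    rows <- m[assignment$group == g, , drop = FALSE]
    n <- nrow(rows)
    data.frame(group = g, hour = 9:16,
               mean = colMeans(rows),
               se = if (n == 1L) rep(0, 8) else apply(rows, 2, stats::sd) / sqrt(n),
               n = n)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-cluster five-number summaries of environmental covariates
#'
#' @param assignment a `cluster_assignment` whose `label`s are
#'   `"<date> <site>"` site-day identifiers.
#' @param features a `daily_features` table joinable on site-day.
#' @param vars covariates to summarize.
#' @return data.frame: `group`, `variable`, `min`, `q1`, `median`, `q3`,
#'   `max`, `n`; quartiles use the linear-interpolation definition.
#' @export
cluster_covariate_summary <- function(assignment, features,
                                      vars = c("wind", "irradiance", "temp")) {
  key <- paste(features$date, features$site)
  idx <- match(assignment$label, key)
  if (anyNA(idx)) {
    message(sum(is.na(idx)), " site-day(s) without matching features skipped")
  }
  out <- list()
  for (g in sort(unique(assignment$group))) {
    rows <- idx[assignment$group == g]
    rows <- rows[!is.na(rows)]
    for (v in vars) {
      x <- features[[v]][rows]
      x <- x[!is.na(x)]
      if (!length(x)) next
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      out[[length(out) + 1L]] <-
        data.frame(group = g, variable = v, min = min(x), q1 = q[1],
                   median = q[2], q3 = q[3], max = max(x), n = length(x))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
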