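#' @title Environmental-driver classification of diel clusters
#' @description Collinearity screening, maximum-likelihood multinomial
#'   logistic regression (Newton iterations on the softmax likelihood, with
#'   observed-information Wald tests), and the column-normalized
#'   percent-correct confusion table under the resubstitution protocol.
#' @name lakechla-drivers
NULL

#' Screen collinear predictors
#'
#' Iteratively removes one member of the highest-correlated pair with
#' `|r| >= threshold`: the member with the larger mean absolute correlation
#' to all other predictors is dropped (ties: the later column). Zero-variance
#' columns are dropped with a warning. Non-numeric columns (e.g. the site
#' factor) never enter the correlation and are always retained.
#'
#' @param features data.frame of candidate predictors.
#' @param threshold absolute-correlation cutoff (default 0.6).
#' @return character vector of retained column names, with attribute
#'   `dropped` recording each removal.
#' @export
screen_collinear <- function(features, threshold = 0.6) {
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  keep_always <- setdiff(names(features), num)
  dropped <- character(0)
  zv <- num[vapply(num, function(c)
    stats::var(features[[c]], na.rm = TRUE) == 0 ||
      all(is.na(features[[c]])), logical(1))]
  if (length(zv)) {
    warning("dropping zero-variance predictor(s): ",
            paste(zv, collapse = ", "), call. = FALSE)
    dropped <- c(dropped, zv)
    num <- setdiff(num, zv)
  }
  while (length(num) >= 2L) {
    r <- abs(stats::cor(features[num], use = "pairwise.complete.obs"))
    diag(r) <- 0
    if (max(r, na.rm = TRUE) < threshold) break
    pair <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cand <- num[pair]
    meanr <- colMeans(r, na.rm = TRUE)[pair]
    drop <- if (meanr[1] > meanr[2]) cand[1]
    else if (meanr[2] > meanr[1]) cand[2]
    else cand[which.max(match(cand, names(features)))]
    dropped <- c(dropped, drop)
    num <- setdiff(num, drop)
  }
  structure(c(num, keep_always), dropped = dropped)
}

# ---- softmax maximum likelihood -------------------------------------------

softmax_prob <- function(X, beta) {
  eta <- cbind(0, X %*% beta)             # reference class first, eta = 0
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta)
  p / rowSums(p)
}

#' Fit a multinomial logistic model of cluster membership
#'
#' Maximum-likelihood softmax regression fitted by Newton iterations with
#' step halving (so the log-likelihood never decreases), started from zero
#' coefficients — the fit is fully deterministic. Predictors are z-scored
#' internally for the optimization and coefficients (and their covariance)
#' are mapped back to the original scale exactly. The reference class is the
#' lowest group number. Near-singular observed information (as happens with
#' small or separable clusters) triggers a tiny-ridge refit (L2 = 1e-6) and
#' is reported via `converged`/`ridged`.
#'
#' @param features data.frame of predictors (numeric and/or factor).
#' @param labels cluster group labels (coercible to factor; numeric labels
#'   are ordered numerically so the reference is the lowest group number).
#' @param maxit Newton iteration cap.
#' @param tol convergence tolerance on the gradient max-norm.
#' @return list of class `multinomial_model`: `classes`, `reference_class`,
#'   `coefficients` ((K-1) x (p+1)), `standard_errors`, `vcov`, `loglik`,
#'   `loglik_trace`, `converged`, `ridged`, plus the internal design.
#' @export
fit_multinomial <- function(features, labels, maxit = 200L, tol = 1e-8) {
  labels <- as.vector(labels)
  lev <- unique(labels)
  lev <- if (!anyNA(suppressWarnings(as.numeric(lev))))
    lev[order(as.numeric(lev))] else sort(lev)
  lev <- as.character(lev)
  y <- factor(labels, levels = lev)
  if (nlevels(y) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (any(table(y) < 1L)) stop("every class needs an observation", call. = FALSE)
  mf <- stats::model.frame(~ ., data = as.data.frame(features),
                           na.action = stats::na.omit)
  if (nrow(mf) < length(y)) {
    keep <- as.integer(rownames(mf))
    y <- y[keep]
  }
  X <- stats::model.matrix(~ ., data = mf)
  terms_orig <- colnames(X)
  # internal z-scoring (intercept untouched); exact back-transform later
  ctr <- colMeans(X); ctr[1] <- 0
  scl <- apply(X, 2, stats::sd); scl[1] <- 1; scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  K <- nlevels(y); p1 <- ncol(Z); n <- nrow(Z)
  Y <- stats::model.matrix(~ y - 1)       # n x K indicator
  fit <- softmax_newton(Z, Y, lambda = 0, maxit = maxit, tol = tol)
  ridged <- FALSE
  info_ok <- is.finite(fit$logdet) && fit$mineig > 1e-10
  if (!info_ok) {
    fit <- softmax_newton(Z, Y, lambda = 1e-6, maxit = maxit, tol = tol)
    ridged <- TRUE
  }
  # back-transform: eta = Z b_std = X b_orig with the linear map below
  # slope_orig = slope_std / scl; int_orig = int_std - sum(slope_std*ctr/scl)
  Tm <- diag(1 / scl)
  Tm[1, ] <- -ctr / scl
  Tm[1, 1] <- 1
  B <- matrix(fit$beta, p1, K - 1L)
  Borig <- Tm %*% B
  # covariance: theta_orig = (I_{K-1} (x) Tm) theta_std
  bigT <- kronecker(diag(K - 1L), Tm)
  V <- if (all(is.finite(fit$vcov))) bigT %*% fit$vcov %*% t(bigT)
  else fit$vcov
  se <- matrix(sqrt(pmax(diag(V), 0)), p1, K - 1L)
  coefficients <- t(Borig); standard_errors <- t(se)
  dimnames(coefficients) <- dimnames(standard_errors) <-
    list(lev[-1], terms_orig)
  structure(list(classes = lev, reference_class = lev[1],
                 coefficients = coefficients,
                 standard_errors = standard_errors, vcov = V,
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 converged = fit$converged, ridged = ridged,
                 terms = terms_orig, X = X, y = y),
            class = "multinomial_model")
}

softmax_newton <- function(Z, Y, lambda, maxit, tol) {
  n <- nrow(Z); p1 <- ncol(Z); K <- ncol(Y)
  npar <- p1 * (K - 1L)
  beta <- matrix(0, p1, K - 1L)
  ll <- function(beta) {
    P <- softmax_prob(Z, beta)
    sum(Y * log(pmax(P, 1e-300))) - lambda * sum(beta^2) / 2
  }
  cur <- ll(beta); trace <- cur; converged <- FALSE
  H <- NULL
  for (it in seq_len(maxit)) {
    P <- softmax_prob(Z, beta)
    G <- numeric(npar); H <- matrix(0, npar, npar)
    for (c in 2:K) {
      gi <- crossprod(Z, Y[, c] - P[, c]) - lambda * beta[, c - 1L]
      G[((c - 2L) * p1 + 1L):((c - 1L) * p1)] <- gi
      for (d in 2:K) {
        wcd <- P[, c] * ((c == d) - P[, d])
        blk <- crossprod(Z * wcd, Z)
        if (c == d) blk <- blk + lambda * diag(p1)
        H[((c - 2L) * p1 + 1L):((c - 1L) * p1),
          ((d - 2L) * p1 + 1L):((d - 1L) * p1)] <- blk
      }
    }
    if (max(abs(G)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H + 1e-12 * diag(npar), G),
                     error = function(e) G / max(1, max(abs(G))))
    # step halving: likelihood must not decrease
    s <- 1
    repeat {
      cand <- beta + s * matrix(step, p1, K - 1L)
      lc <- ll(cand)
      if (lc >= cur - 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    if (lc < cur + 1e-12 && s < 1e-8) break  # no progress
    beta <- cand; cur <- lc; trace <- c(trace, cur)
  }
  eh <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  vc <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, npar, npar))
  list(beta = beta, loglik = cur, trace = trace, converged = converged,
       vcov = vc, logdet = suppressWarnings(sum(log(eh))),
       mineig = min(eh) / max(abs(eh)))
}

#' @export
print.multinomial_model <- function(x, ...) {
  cat(sprintf("<multinomial_model> %d classes (reference %s), %d terms, logLik %.3f%s\n",
              length(x$classes), x$reference_class, ncol(x$coefficients),
              x$loglik,
              if (!x$converged) " [not converged]" else if (x$ridged)
                " [ridged]" else ""))
  invisible(x)
}

#' Class-membership probabilities and predicted classes
#' @param object a `multinomial_model`.
#' @param newdata optional data.frame of predictors; default training data.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.multinomial_model <- function(object, newdata = NULL,
                                      type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else
    stats::model.matrix(~ ., data = as.data.frame(newdata))
  X <- X[, object$terms, drop = FALSE]
  P <- softmax_prob(X, t(object$coefficients))
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Two-tailed Wald z tests for every coefficient
#'
#' `z = estimate / SE` with SEs from the inverse observed information;
#' `p = 2 (1 - Phi(|z|))`. Reported missing with a warning when the
#' information matrix was singular.
#'
#' @param model a `multinomial_model`.
#' @return data.frame: `class`, `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_tests <- function(model) {
  est <- model$coefficients; se <- model$standard_errors
  if (any(!is.finite(se))) {
    warning("singular information: some Wald p-values reported missing",
            call. = FALSE)
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(class = rep(rownames(est), ncol(est)),
                    term = rep(colnames(est), each = nrow(est)),
                    estimate = as.vector(est), se = as.vector(se),
                    z = as.vector(z), p = as.vector(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Column-normalized percent-correct confusion table
#'
#' Resubstitution evaluation (no train/test split, matching the small-n
#' protocol): predicted class is the argmax probability on the training
#' data; each cell is the percentage of that true cluster's days predicted as
#' the row cluster, so every column sums to 100 and the diagonal is the
#' per-cluster percent correct.
#'
#' @param model a `multinomial_model`.
#' @param features,labels optionally, data to evaluate on (default: training
#'   data).
#' @return list of class `confusion_table`: `percent` (predicted x true),
#'   `counts`, `n_per_class`.
#' @export
confusion_table <- function(model, features = NULL, labels = NULL) {
  if (is.null(features)) {
    pred <- predict(model)
    truth <- as.character(model$y)
  } else {
    pred <- predict(model, newdata = features)
    truth <- as.character(labels)
  }
  lev <- model$classes
  counts <- table(factor(pred, levels = lev), factor(truth, levels = lev))
  ncol_ <- colSums(counts)
  percent <- sweep(counts, 2, pmax(ncol_, 1L), "/") * 100
  structure(list(percent = unclass(percent), counts = unclass(counts),
                 n_per_class = ncol_),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> percent of each true cluster (columns) predicted as row cluster:\n")
  print(round(x$percent, 1))
  cat("n per true cluster:", paste(x$n_per_class, collapse = ", "), "\n")
  invisible(x)
}
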