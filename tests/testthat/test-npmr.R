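micro_model <- function() {
  npmr_model(data.frame(x = c(0, 1, 2), y = c(0, 1, 2)), "y", "x", 0.5,
             min_neighborhood = 0)
}

test_that("the three-point worked example reproduces hand kernel arithmetic", {
  m <- micro_model()
  est <- attr(loo_xr2(m), "estimates")
  # hand values: interior point weights e^-2 to both neighbors; endpoints
  # (1 e^-2 + 2 e^-8)/(e^-2 + e^-8) and its mirror
  e2 <- exp(-2); e8 <- exp(-8)
  expect_equal(est, c((1 * e2 + 2 * e8) / (e2 + e8), 1,
                      (1 * e2 + 0 * e8) / (e2 + e8)), tolerance = 1e-12)
  expect_equal(m$xr2, 1 - (2 * ((1 * e2 + 2 * e8) / (e2 + e8))^2) / 2,
               tolerance = 1e-12)
  expect_lt(m$xr2, 0)  # cross-validated R2 can be negative
})

test_that("kernel limits: tiny tolerance interpolates, huge tolerance averages", {
  d <- data.frame(x = c(0, 1, 2), y = c(5, 7, 11))
  tiny <- npmr_model(d, "y", "x", 1e-3, min_neighborhood = 0)
  expect_equal(npmr_estimate(tiny, data.frame(x = 1)), 7)
  huge <- npmr_model(d, "y", "x", 1e6, min_neighborhood = 0)
  expect_equal(npmr_estimate(huge, data.frame(x = 1)), mean(d$y),
               tolerance = 1e-9)
  # no-estimate when the neighborhood threshold is not met
  strict <- npmr_model(d, "y", "x", 0.1, min_neighborhood = 0.5)
  expect_true(is.na(npmr_estimate(strict, data.frame(x = 10))))
})

test_that("estimator, LOO and neighborhood sizes match a naive double-loop oracle", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(10:50, 1); p <- sample(1:3, 1)
    x <- matrix(runif(n * p, 0, 10), n,
                dimnames = list(NULL, paste0("v", 1:p)))
    y <- rnorm(n)
    tol <- runif(p, 0.5, 3)
    d <- data.frame(x, y = y)
    m <- npmr_model(d, "y", paste0("v", 1:p), tol, min_neighborhood = 0)
    q <- matrix(runif(5 * p, 0, 10), 5, dimnames = list(NULL, paste0("v", 1:p)))
    expect_equal(npmr_estimate(m, q),
                 naive_npmr_estimate(x, y, tol, q), tolerance = 1e-12)
    expect_equal(neighborhood_sizes(m)$sizes,
                 naive_neighborhood(x, tol), tolerance = 1e-12)
    expect_equal(m$xr2, naive_loo_xr2(x, y, tol), tolerance = 1e-12)
  }
})

test_that("estimates are invariant to affine predictor rescaling with rescaled tolerance", {
  set.seed(32)
  d <- data.frame(x = runif(30, 0, 10), y = rnorm(30))
  m1 <- npmr_model(d, "y", "x", 1.5, min_neighborhood = 0)
  d2 <- data.frame(x = 3 * d$x + 7, y = d$y)
  m2 <- npmr_model(d2, "y", "x", 4.5, min_neighborhood = 0)
  expect_equal(npmr_estimate(m1, data.frame(x = c(2, 5, 8))),
               npmr_estimate(m2, data.frame(x = 3 * c(2, 5, 8) + 7)),
               tolerance = 1e-12)
  expect_equal(m1$xr2, m2$xr2, tolerance = 1e-12)
})

test_that("free search finds the active predictor first and obeys its stopping rule", {
  set.seed(33)
  n <- 70
  d <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  d$y <- sin(d$a / 2) + 0.5 * d$a
  s <- free_search(d, "y", c("b", "a"))
  expect_equal(s$best$predictors[1], "a")
  # improvement threshold 1.0: single-predictor model always returned
  s1 <- free_search(d, "y", c("a", "b"), min_gain = 1.0)
  expect_length(s1$best$predictors, 1)
  # adding a pure-noise duplicate never improves the selected model
  d$a_noise <- d$a + rnorm(n, 0, 3)
  s2 <- free_search(d, "y", c("a", "a_noise"))
  expect_lte(length(s2$best$predictors), 2)
  expect_gte(s2$xr2_by_size[1], max(s2$xr2_by_size) - 0.02)
})

test_that("free search equals an exhaustive oracle on a small grid", {
  set.seed(34)
  n <- 40
  d <- data.frame(a = runif(n, 0, 5), b = runif(n, 0, 5))
  d$y <- d$a^2 - 2 * d$b + rnorm(n, 0, 0.5)
  grid <- c(0.05, 0.1, 0.2, 0.45, 1.0)
  s <- free_search(d, "y", c("a", "b"), grid = grid, min_gain = -Inf,
                   min_neighborhood = 0, coverage = 0)
  # exhaustive oracle: best model per size over every subset and tolerance
  # combination
  exhaustive <- function(sets) {
    best <- list(xr2 = -Inf)
    for (set in sets) {
      tls <- lapply(set, function(v) grid * diff(range(d[[v]])))
      combos <- expand.grid(tls)
      for (i in seq_len(nrow(combos))) {
        xr2 <- naive_loo_xr2(d[, set, drop = FALSE], d$y,
                             as.numeric(combos[i, ]))
        if (xr2 > best$xr2) best <- list(set = set,
                                         tol = as.numeric(combos[i, ]),
                                         xr2 = xr2)
      }
    }
    best
  }
  b1 <- exhaustive(list("a", "b"))
  b2 <- exhaustive(list(c("a", "b")))
  expect_equal(s$xr2_by_size[1], b1$xr2, tolerance = 1e-10)
  expect_equal(s$by_size[[1]]$predictors, b1$set)
  expect_equal(s$xr2_by_size[2], b2$xr2, tolerance = 1e-10)
  expect_equal(sort(unname(s$by_size[[2]]$tolerances)), sort(b2$tol),
               tolerance = 1e-10)
})

test_that("sensitivity is 0 for absent predictors and ~1 for a near-interpolated line", {
  set.seed(35)
  d <- data.frame(x = seq(0, 10, length.out = 60))
  d$y <- d$x
  m <- npmr_model(d, "y", "x", 0.05, min_neighborhood = 0)
  sen <- npmr_sensitivity(m, c("x", "unused"))
  expect_equal(sen$sensitivity[sen$predictor == "unused"], 0)
  expect_equal(sen$sensitivity[sen$predictor == "x"], 1, tolerance = 0.05)
})

test_that("permutation test guards its inputs and detects strong signal", {
  set.seed(36)
  d <- data.frame(x = runif(50, 0, 10))
  d$y <- sin(d$x) + rnorm(50, 0, 0.05)
  m <- npmr_fit(d, "y", "x")
  expect_error(npmr_permutation_test(m, n_perm = 0), "n_perm")
  pt <- npmr_permutation_test(m, n_perm = 99, seed = 2)
  expect_equal(pt$p, 1 / 100)  # minimum attainable p
})
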