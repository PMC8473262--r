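test_that("Sorensen distance matches the direct formula and stays in [0, 1]", {
  m <- rbind(a = c(2, 1, 0), b = c(1, 1, 1), c = c(2, 1, 0))
  d <- as.matrix(sorensen_matrix(m))
  expect_equal(d["a", "b"], 1 / 3, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_equal(as.vector(sorensen_matrix(disjoint)), 1)
  set.seed(4)
  r <- matrix(runif(80), 10)
  dr <- as.matrix(sorensen_matrix(r))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_true(isSymmetric(dr))
  expect_error(sorensen_matrix(rbind(c(0, 0), c(1, 1))), "all-zero")
})

test_that("flexible-beta follows the Lance-Williams update and known reductions", {
  # after merging the closest pair (d = 1), the new-to-k distance must be
  # 0.625 * (2 + 4) - 0.25 * 1 = 3.5
  d <- matrix(c(0, 1, 2,
                1, 0, 4,
                2, 4, 0), 3, byrow = TRUE)
  tree <- flexible_beta_cluster(d, beta = -0.25)
  expect_equal(tree$height, c(1, 3.5))
  expect_equal(tree$merge[1, ], c(-2, -1))
  # beta = 0 reduces to WPGMA (hclust's mcquitty linkage)
  set.seed(12)
  x <- matrix(runif(36), 6)
  dd <- dist(x)
  t0 <- flexible_beta_cluster(dd, beta = 0)
  h <- hclust(dd, method = "mcquitty")
  expect_equal(t0$height, h$height, tolerance = 1e-12)
})

test_that("agglomeration agrees with brute-force and library oracles", {
  set.seed(99)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    dm <- as.matrix(dist(matrix(runif(n * 3), n)))
    tree <- flexible_beta_cluster(dm, beta = -0.25)
    oracle <- brute_flexible_beta(dm, beta = -0.25)
    expect_equal(tree$height, oracle$height, tolerance = 1e-12)
    expect_equal(tree$merge, oracle$merge)
  }
  skip_if_not_installed("cluster")
  set.seed(100)
  dm <- dist(matrix(runif(8 * 4), 8))
  tree <- flexible_beta_cluster(dm, beta = -0.25)
  ag <- cluster::agnes(dm, method = "flexible", par.method = 0.625)
  expect_equal(sort(tree$height), sort(ag$height), tolerance = 1e-10)
})

test_that("cutting partitions the leaves and numbers groups by first member", {
  set.seed(5)
  dm <- dist(matrix(runif(7 * 2), 7))
  tree <- flexible_beta_cluster(dm)
  # k = n: every leaf its own group, numbers = row indices
  all_single <- cut_to_groups(tree, 7)
  expect_equal(all_single$group, 1:7)
  # k = 1: one group numbered 1
  expect_equal(unique(cut_to_groups(tree, 1)$group), 1)
  for (k in 2:6) {
    asg <- cut_to_groups(tree, k)
    expect_equal(length(unique(asg$group)), k)
    expect_equal(nrow(asg), 7)
    # group number is the first member's row index
    for (g in unique(asg$group))
      expect_equal(min(asg$row[asg$group == g]), g)
  }
  expect_error(cut_to_groups(tree, 0), "k must lie")
})

test_that("planted two-shape profiles are recovered at k = 2", {
  pp <- planted_profiles(n = 80, noise_sd = 0.05, seed = 17)
  tree <- flexible_beta_cluster(sorensen_matrix(pp$m), beta = -0.25)
  asg <- cut_to_groups(tree, 2)
  agree <- (asg$group == asg$group[1]) == (pp$labels == pp$labels[1])
  accuracy <- max(mean(agree), 1 - mean(agree))
  expect_gte(accuracy, 0.9)
})

test_that("cluster profile means and standard errors follow the definitions", {
  ts <- as.POSIXct("2019-07-01 09:00", tz = "UTC") + 0:7 * 3600
  mk_day <- function(site, day, v) data.frame(
    timestamp = ts + day * 86400, site = site, chla = v)
  conc <- c(10, 8, 6, 4, 4, 6, 8, 10)
  h <- rbind(mk_day("a", 0, conc), mk_day("a", 1, conc),
             mk_day("a", 2, rev(seq(2, 16, 2))))
  prof <- diel_profiles(chla_obs(h$timestamp, h$site, h$chla))
  asg <- data.frame(row = 1:3, label = paste(prof$date, prof$site),
                    group = c(1, 1, 3))
  cp <- cluster_profiles(asg, prof)
  # two identical members: SE = 0; singleton: SE = 0 by convention
  expect_equal(cp$se[cp$group == 1], rep(0, 8))
  expect_equal(cp$se[cp$group == 3], rep(0, 8))
  expect_equal(cp$mean[cp$group == 1], conc / 10)
  expect_equal(cp$n[cp$group == 1], rep(2, 8))
  # concave cluster mean dips at the midday bins
  expect_equal(which.min(cp$mean[cp$group == 1]), 4)
})

test_that("covariate summaries use linear-interpolation quartiles", {
  feats <- data.frame(date = as.Date("2019-07-01") + 0:4, site = "a",
                      wind = 1:5, irradiance = 11:15, temp = 21:25)
  asg <- data.frame(row = 1:5, label = paste(feats$date, feats$site),
                    group = 1)
  cs <- cluster_covariate_summary(asg, feats)
  w <- cs[cs$variable == "wind", ]
  expect_equal(unlist(w[c("q1", "median", "q3")], use.names = FALSE),
               c(2, 3, 4))
  expect_equal(w$min, 1); expect_equal(w$max, 5)
  # singleton cluster: all five numbers equal
  asg1 <- asg[1, ]
  cs1 <- cluster_covariate_summary(asg1, feats)
  expect_true(all(apply(cs1[, c("min", "q1", "median", "q3", "max")], 1,
                        function(r) diff(range(r)) == 0)))
})

test_that("concave clusters sit at higher irradiance than convex in a planted scenario", {
  cfg <- scenario_config(
    noise_cv = 0, weather_noise = list(temp_sd = 0.3, wind_sd = 0.3,
                                       rain_p = 0),
    end = as.Date("2019-08-15"), seed = 23L,
    diel_shapes = list(trasimeno = c(concave = 1, convex = 0, flat = 0),
                       curonian = c(concave = 0, convex = 1, flat = 0),
                       vortsjarv = c(concave = 0.5, convex = 0.5, flat = 0)))
  w <- generate_weather(cfg)
  ct <- generate_chla_truth(cfg, w)
  hourly <- aggregate_series(ct$obs, "hourly")
  prof <- common_days(diel_profiles(hourly))
  tree <- flexible_beta_cluster(sorensen_matrix(prof), beta = -0.25)
  asg <- cut_to_groups(tree, 2)
  feats <- do.call(rbind, lapply(names(w), function(s)
    as.data.frame(antecedent_features(w[[s]]))))
  cs <- cluster_covariate_summary(asg, feats)
  truth_shape <- ct$truth$daily$diel_shape[
    match(asg$label, paste(ct$truth$daily$date, ct$truth$daily$site))]
  conc_group <- names(which.max(table(asg$group[truth_shape == "concave"])))
  irr <- cs[cs$variable == "irradiance", ]
  expect_gt(irr$median[irr$group == as.integer(conc_group)],
            max(irr$median[irr$group != as.integer(conc_group)]))
})
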