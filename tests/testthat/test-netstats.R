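test_that("relative frequency bins follow the definition", {
  bf <- bin_relative_frequency(c(1, 1, 1, 1, 5, 5, 5, 5, 5),
                               c(1, 1, 1, 0, 0, 0, 0, 0, 0), n_bins = 2)
  expect_equal(bf$relative_frequency, c(3 / 4, 0))
  expect_equal(sum(bf$n_present + bf$n_absent), 9)
  # tiered measures get one bin per distinct value regardless of n_bins
  vals <- rep(0:6, times = 7:1)
  bf7 <- bin_relative_frequency(vals, rep(0, length(vals)), n_bins = 10)
  expect_equal(nrow(bf7), 7)
  expect_true(attr(bf7, "tiered"))
  # empty bins carry NA frequency under equal-width binning
  bfe <- bin_relative_frequency(c(rep(0, 5), rep(10, 5), 1:20 / 100),
                                rep(0:1, 15), n_bins = 10)
  expect_true(any(is.na(bfe$relative_frequency)))
  expect_equal(sum(bfe$n_present + bfe$n_absent), 30)
  # floating-point noise in tier differences does not split tiers
  tiers <- abs(outer(100 * (1 + 4 * (0:6) / 6), 100 * (1 + 4 * (0:6) / 6),
                     `-`))
  bft <- bin_relative_frequency(as.vector(tiers),
                                rep(0, length(tiers)), n_bins = 10)
  expect_equal(nrow(bft), 7)
})

test_that("rank correlation is exact for few bins and matches oracles", {
  expect_equal(spearman_correlation(1:5, (1:5)^2)$rho, 1)
  expect_equal(spearman_correlation(1:5, 5:1)$rho, -1)
  # a perfect correlation across four tiers cannot beat p = 0.083
  r4 <- spearman_correlation(1:4, 4:1)
  expect_equal(r4$p_value, 2 / factorial(4), tolerance = 1e-12)
  expect_gt(r4$p_value, 0.05)
  r5 <- spearman_correlation(1:5, 5:1)
  expect_equal(r5$p_value, 2 / factorial(5), tolerance = 1e-12)
  # exhaustive oracle for n <= 6: enumerate all rank permutations here
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_all(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  for (n in 4:6) {
    set.seed(n)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- spearman_correlation(x, y)
    rho_obs <- cor(rank(x), rank(y))
    rhos <- vapply(perm_all(rank(x)), function(p) cor(p, rank(y)),
                   numeric(1))
    expect_equal(got$rho, rho_obs)
    expect_equal(got$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
    # and against the exact distribution in cor.test (no ties here)
    ct <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-12)
  }
  # undefined cases
  expect_true(is.na(spearman_correlation(1:2, 2:1)$rho))
  expect_true(is.na(spearman_correlation(1:5, rep(1, 5))$rho))
  # NA bins are dropped before correlating
  expect_equal(spearman_correlation(1:6, c(6:3, NA, 1))$n, 5)
})

test_that("the left-tailed sign test matches its normal approximation", {
  st <- sign_test_left(rep(0.001, 100), 0.05)
  expect_equal(st$z, -9.9)
  expect_equal(st$p_value, 2.08e-23, tolerance = 1e-2)
  bal <- sign_test_left(c(rep(0.01, 50), rep(0.99, 50)), 0.05)
  expect_gte(bal$p_value, 0.05)
  expect_error(sign_test_left(numeric(0)), "p-values")
  # ties at the threshold are discarded
  expect_equal(sign_test_left(c(0.05, 0.01, 0.01), 0.05)$n, 2)
})

test_that("logistic fits are maximum likelihood with proper nesting", {
  y <- rep(c(0, 1), 50)
  f0 <- fit_logistic(y, NULL, "null")
  expect_equal(f0$log_likelihood, 100 * log(0.5))
  set.seed(2)
  x1 <- rnorm(100)
  x2 <- rnorm(100)
  y2 <- rbinom(100, 1, plogis(0.5 * x1))
  ll0 <- fit_logistic(y2, NULL)$log_likelihood
  ll1 <- fit_logistic(y2, data.frame(x1))$log_likelihood
  ll2 <- fit_logistic(y2, data.frame(x1, x2))$log_likelihood
  expect_gte(ll1, ll0)
  expect_gte(ll2, ll1)
  expect_error(fit_logistic(rep(1, 10), NULL), "both classes")
  # 4-point dataset against a coarse-to-fine grid-search oracle
  xt <- c(-1, -0.2, 0.4, 1.3)
  yt <- c(0, 1, 0, 1)
  fit <- fit_logistic(yt, data.frame(x = xt))
  grid_ll <- function(b0s, b1s) {
    z <- zscore(xt)
    best <- -Inf
    for (b0 in b0s) for (b1 in b1s) {
      p <- plogis(b0 + b1 * z)
      ll <- sum(yt * log(p) + (1 - yt) * log(1 - p))
      if (ll > best) {
        best <- ll
        arg <- c(b0, b1)
      }
    }
    list(ll = best, arg = arg)
  }
  g1 <- grid_ll(seq(-3, 3, 0.1), seq(-3, 3, 0.1))
  g2 <- grid_ll(seq(g1$arg[1] - 0.1, g1$arg[1] + 0.1, 0.001),
                seq(g1$arg[2] - 0.1, g1$arg[2] + 0.1, 0.001))
  expect_equal(fit$log_likelihood, g2$ll, tolerance = 1e-4)
})

test_that("McFadden's pseudo-R2 measures likelihood improvement", {
  expect_equal(mcfadden_r2(-50, -50), 0)
  expect_equal(mcfadden_r2(-25, -50), 0.5)
  expect_equal(mcfadden_r2(-1e-9, -50), 1, tolerance = 1e-9)
  expect_equal(mcfadden_r2(-25, -50, printed_formula = TRUE), 0.5)
  expect_error(mcfadden_r2(-25, 0), "negative")
})

test_that("the per-instance report matches direct computation on a toy", {
  # 4 areas on a line, densities 1..4, unit spacing; synapses chosen so
  # area connectivity is: 1->2, 2->1, 1->3, 3->4 (4 of 12 possible)
  na <- rep(1:4, each = 2)
  syn <- data.frame(source_neuron_id = c(1, 3, 2, 5),
                    target_neuron_id = c(3, 1, 6, 8),
                    time_step = 1:4)
  co <- aggregate_connectome(syn, na, n_areas = 4)
  areas <- data.frame(area_id = 1:4, density = 1:4)
  pairs <- expand.grid(target = 1:4, source = 1:4)
  pairs <- pairs[pairs$source != pairs$target, ]
  meas <- data.frame(
    source = pairs$source, target = pairs$target,
    density_diff = areas$density[pairs$source] -
      areas$density[pairs$target],
    abs_density_diff = abs(areas$density[pairs$source] -
                           areas$density[pairs$target]),
    distance = abs(pairs$source - pairs$target))
  rep <- analyze_instance(co, meas, areas)
  expect_equal(rep$fraction_connected, 4 / 12)
  expect_equal(rep$n_connections, 4)
  expect_equal(rep$n_bins_density, 3)
  # frequencies by |density difference| tier: 3/6, 1/4, 0/2
  bf <- bin_relative_frequency(meas$abs_density_diff,
                               co$exists[cbind(meas$source, meas$target)])
  expect_equal(bf$relative_frequency, c(3 / 6, 1 / 4, 0 / 2))
  expect_equal(rep$rho_density, -1)
  expect_equal(rep$p_density, 2 / 6, tolerance = 1e-12)   # 3 bins exact
  # degree: computed afferent + efferent per area
  expect_equal(area_degree(co), c(3L, 2L, 2L, 1L))
  # logistic nesting holds on the toy as everywhere
  expect_gte(rep$r2_both, max(rep$r2_distance, rep$r2_density) - 1e-12)
})

test_that("aggregation reports medians and cross-instance sign tests", {
  rep1 <- data.frame(fraction_connected = c(0.4, 0.5, 0.6),
                     n_connections = c(10, 12, 14),
                     rho_distance = c(-0.9, -0.8, -1),
                     p_distance = c(0.01, 0.02, 0.001),
                     rho_density = c(-1, -0.9, -0.95),
                     p_density = c(0.01, 0.01, 0.04),
                     n_bins_density = 5,
                     r2_distance = c(0.2, 0.25, 0.3),
                     r2_density = c(0.1, 0.15, 0.2),
                     r2_both = c(0.3, 0.35, 0.4),
                     rho_degree = c(-0.5, -0.4, -0.6),
                     p_degree = c(0.2, 0.3, 0.4))
  agg <- aggregate_instances(rep1)
  expect_equal(agg$median_fraction_connected, 0.5)
  expect_equal(agg$median_rho_density, -0.95)
  expect_equal(agg$sign_p_density, sign_test_left(rep1$p_density)$p_value)
  expect_gt(agg$sign_p_degree, 0.05)
})
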