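# Estimators: log-linear k_obs, half-lives, the nonlinear k1 fit, Monte
# Carlo propagation, and the ligation censoring rule.

test_that("fit_kobs recovers an exact exponential rate and its inverse", {
  f <- fit_kobs(decay_tc(1.81), "primer")
  expect_equal(f$k_obs, 1.81, tolerance = 1e-6)
  expect_equal(f$intercept, 0, tolerance = 1e-9)
  expect_equal(f$n_points, 11L)

  # constant signal: zero rate
  f0 <- fit_kobs(data.frame(t_h = 0:5, primer = rep(0.8, 6)), "primer")
  expect_equal(f0$k_obs, 0, tolerance = 1e-12)

  # half_life and its inverse compose to the identity
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(2 * log(2)), 0.5)
  expect_equal(half_life(log(2) / 72), 72)
  for (k in c(0.01, 0.5, 3)) expect_equal(log(2) / half_life(k), k)
  expect_error(half_life(0), "> 0")
})

test_that("fit_kobs recovers a slow rate from noisy data within 15%", {
  set.seed(101)
  k <- 0.0288
  times <- seq(0, 72, by = 8)
  p <- exp(-k * times) * exp(stats::rnorm(length(times), 0, 0.05))
  f <- fit_kobs(data.frame(t_h = times, primer = p), "primer")
  expect_lt(abs(f$k_obs - k) / k, 0.15)
})

test_that("fit_kobs excludes non-positive points with a warning", {
  tc <- decay_tc(1)
  tc$primer[5] <- 0
  expect_warning(f <- fit_kobs(tc, "primer"), "non-positive")
  expect_equal(f$n_excluded, 1L)
  expect_equal(f$k_obs, 1, tolerance = 1e-6)
  expect_error(
    suppressWarnings(fit_kobs(data.frame(t_h = 0:2, primer = c(1, 0, 0)),
                              "primer")),
    "at least 2")
})

test_that("fit_k1 round-trips noiseless generator output on a grid", {
  for (k1 in c(0.1, 1, 12)) {
    for (k2 in c(0.2, 0.7)) {
      for (k3 in c(0.05, 0.118, 9)) {
        for (p0 in c(0.26, 0.45, 0.60)) {
          tc <- ext_timecourse(k1 = k1, k2 = k2, k3 = k3, p_gly0 = p0)
          f <- fit_k1(tc, k2, k3, p0)
          expect_true(f$converged)
          expect_lt(abs(f$k1 - k1) / k1, 1e-4)
        }
      }
    }
  }
})

test_that("fit_k1 flags the zero boundary when no NP+1 forms", {
  # aminoacyl pool only hydrolyzes; native pool only extends: k1 = 0 truth
  tc <- ext_timecourse(k1 = 0, k2 = 0.7, k3 = 0.5, p_gly0 = 0.4)
  f <- fit_k1(tc, 0.7, 0.5, 0.4)
  expect_equal(f$k1, 0, tolerance = 1e-6)
  expect_true(f$boundary)
})

test_that("fit_k1 median relative bias stays below 10% at 5% band noise", {
  biases <- vapply(1:20, function(i) {
    tc <- ext_timecourse(replicates = 3,
                         noise = noise_model(sd_mult = 0.05),
                         seed = 1000L + i)
    f <- fit_k1(tc, 0.7, 0.118, 0.4)
    (f$k1 - 12) / 12
  }, numeric(1))
  expect_lt(stats::median(abs(biases)), 0.10)
})

test_that("Monte Carlo propagation is seed-reproducible and degenerates", {
  tc <- ext_timecourse()
  zero <- uncertainty_spec(c(0.4, 0), c(0.7, 0), c(0.118, 0),
                           n_draws = 25, seed = 5)
  fz <- mc_propagate(tc, zero)
  expect_equal(fz$mc_sd, 0)
  expect_equal(fz$k1, fit_k1(tc, 0.7, 0.118, 0.4)$k1)

  spec <- uncertainty_spec(c(0.4, 0.05), c(0.7, 0.1), c(0.118, 0.02),
                           n_draws = 200, seed = 9)
  f1 <- mc_propagate(tc, spec)
  f2 <- mc_propagate(tc, spec)
  expect_identical(f1$k1, f2$k1)
  expect_identical(f1$mc_sd, f2$mc_sd)
  expect_identical(c(f1$q16, f1$q84), c(f2$q16, f2$q84))
  expect_gt(f1$mc_sd, 0)
  expect_lt(abs(f1$k1 - 12) / 12, 0.05)
  expect_error(uncertainty_spec(c(0.4, 0), c(0.7, 0), c(0.1, 0),
                                n_draws = 10),
               "seed")
})

test_that("censoring keeps exactly the points where the control is clean", {
  t <- c(0.05, 0.1, 0.25, 0.5, 1.0)
  amino <- data.frame(t_h = t, primer = exp(-t), ligated = 1 - exp(-t))
  ctl <- data.frame(t_h = t, ligated = c(0.001, 0.005, 0.019, 0.030, 0.080))
  kept <- censor_ligation(amino, ctl)
  expect_equal(kept$t_h, t[1:3])
  expect_equal(kept$primer, amino$primer[1:3])

  # all-dirty control: nothing survives
  dirty <- data.frame(t_h = t, ligated = rep(0.02, 5))
  expect_error(censor_ligation(amino, dirty), "censoring")

  # clean control: identity
  clean <- data.frame(t_h = t, ligated = rep(0, 5))
  expect_equal(censor_ligation(amino, clean)$t_h, amino$t_h)

  # mismatched grids rejected
  off <- data.frame(t_h = t + 0.01, ligated = rep(0, 5))
  expect_error(censor_ligation(amino, off), "time grid")
})

test_that("censored output is a subsequence and respects the threshold", {
  set.seed(33)
  for (i in 1:10) {
    t <- sort(stats::runif(8, 0, 2))
    amino <- data.frame(t_h = t, primer = stats::runif(8))
    ctl <- data.frame(t_h = t, ligated = stats::runif(8, 0, 0.05))
    kept <- tryCatch(censor_ligation(amino, ctl), error = function(e) NULL)
    if (is.null(kept)) {
      expect_true(all(ctl$ligated >= 0.02))
    } else {
      expect_true(all(kept$t_h %in% amino$t_h))
      expect_true(all(ctl$ligated[ctl$t_h %in% kept$t_h] < 0.02))
      expect_false(is.unsorted(match(kept$t_h, amino$t_h)))
    }
  }
})

test_that("ligation round trip recovers k1 through censoring", {
  gen <- gen_ligation_experiment(lig_design())
  amino <- to_timecourse(gen$amino, band_map("ligation"))
  ctl <- to_timecourse(gen$control, band_map("ligation"))
  kept <- censor_ligation(amino, ctl)
  f <- fit_k1(kept, 0.3, 0.004, gen$manifest$p_gly0)
  expect_lt(abs(f$k1 - 1.81) / 1.81, 1e-3)
})

test_that("fold_change matches the study's headline ratios", {
  expect_equal(fold_change(1.81, 0.281), 1.81 / 0.281, tolerance = 1e-12)
  expect_gt(fold_change(1.81, 0.281), 6)
  expect_gt(fold_change(12.0, 0.118), 100)
  expect_equal(fold_change(3.7, 3.7), 1)
  expect_error(fold_change(1, 0), "> 0")
})
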