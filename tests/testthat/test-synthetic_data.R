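# Synthetic gel-data generators: determinism, conservation, band structure.

test_that("generators are deterministic under a seed", {
  d <- ext_design(replicates = 3, noise = noise_model(sd_mult = 0.05),
                  seed = 21L)
  g1 <- gen_extension_experiment(d)
  g2 <- gen_extension_experiment(d)
  expect_identical(g1$table, g2$table)
  expect_identical(g1$manifest, g2$manifest)

  d2 <- ext_design(replicates = 3, noise = noise_model(sd_mult = 0.05),
                   seed = 22L)
  expect_false(identical(gen_extension_experiment(d2)$table$intensity,
                         g1$table$intensity))
})

test_that("replicates are independent noise realizations", {
  d <- ext_design(replicates = 3, noise = noise_model(sd_mult = 0.05))
  tab <- gen_extension_experiment(d)$table
  by_rep <- split(tab$intensity, tab$replicate)
  expect_false(identical(by_rep[[1]], by_rep[[2]]))
  expect_false(identical(by_rep[[2]], by_rep[[3]]))
})

test_that("pre-noise band fractions conserve lane mass", {
  d <- ext_design(k1 = 3, k2 = 0.5, k3 = 0.2, p_gly0 = 0.45)
  tab <- gen_extension_experiment(d)$table
  lane_sums <- tapply(tab$intensity, tab$time_h, sum)
  # noiseless lanes: intensities are fractions x a constant total
  expect_true(all(abs(lane_sums / lane_sums[1] - 1) < 1e-9))
})

test_that("hydrolysis generator decays primer_gly and conserves mass", {
  d <- hyd_design(k2 = log(2) / 72, p_gly0 = 0.5)
  g <- gen_hydrolysis_experiment(d)
  tc <- to_timecourse(g$table, band_map("hydrolysis_acidic"))
  expect_equal(tc$primer_gly, 0.5 * exp(-log(2) / 72 * tc$t_h),
               tolerance = 1e-12)
  expect_equal(tc$primer_gly + tc$primer_rna, rep(1, nrow(tc)),
               tolerance = 1e-9)

  # k2 = 0: constant bands
  g0 <- gen_hydrolysis_experiment(hyd_design(k2 = 0))
  tc0 <- to_timecourse(g0$table, band_map("hydrolysis_acidic"))
  expect_equal(tc0$primer_gly, rep(tc0$primer_gly[1], nrow(tc0)))

  # activated substrate is a design error for this experiment type
  expect_error(
    experiment_design("hydrolysis_acidic", "bad", rate_constants(1, 0.1, 0),
                      0.5, c(1, 2), noise = quiet_noise()),
    "k1 and k3")
})

test_that("hydrolysis round trip reproduces the printed-style half-life", {
  g <- gen_hydrolysis_experiment(hyd_design(k2 = log(2) / 72))
  tc <- to_timecourse(g$table, band_map("hydrolysis_acidic"))
  f <- fit_kobs(tc, "primer_gly")
  expect_equal(half_life(f$k_obs), 72, tolerance = 1e-6)
})

test_that("ligation generator pools both +1 products into one band", {
  d <- lig_design(k1 = 1.81, k2 = 0.3, k3 = 0.004, p_gly0 = 0.5)
  g <- gen_ligation_experiment(d)
  tc <- to_timecourse(g$amino, band_map("ligation"))
  truth <- simulate_trajectory(rate_constants(1.81, 0.3, 0.004), 0.5,
                               d$times)
  expect_equal(tc$ligated, truth$p_gly1 + truth$p_rna1, tolerance = 1e-12)
  expect_equal(tc$primer, truth$p_gly + truth$p_rna, tolerance = 1e-12)

  # control arm carries no aminoacylated primer
  ctl <- to_timecourse(g$control, band_map("ligation"))
  ctl_truth <- simulate_trajectory(rate_constants(1.81, 0.3, 0.004), 0,
                                   d$times)
  expect_equal(ctl$ligated, ctl_truth$p_rna1, tolerance = 1e-12)

  # inert control (k3 = 0): censoring keeps every point
  g0 <- gen_ligation_experiment(lig_design(k3 = 0))
  amino0 <- to_timecourse(g0$amino, band_map("ligation"))
  ctl0 <- to_timecourse(g0$control, band_map("ligation"))
  expect_equal(ctl0$ligated, rep(0, nrow(ctl0)))
  expect_equal(censor_ligation(amino0, ctl0)$t_h, amino0$t_h)
})

test_that("undrawn p_gly0 lands in the study's acylation-yield range", {
  for (s in 1:5) {
    d <- ext_design(p_gly0 = NULL, seed = 100L + s)
    m <- gen_extension_experiment(d)$manifest
    expect_gte(m$p_gly0, 0.26)
    expect_lte(m$p_gly0, 0.60)
  }
})

test_that("condition panels concatenate uniquely labelled designs", {
  designs <- list(
    ext_design(condition = "0 mM Mg", k1 = 12, k3 = 0.118, seed = 1L),
    ext_design(condition = "2.5 mM Mg", k1 = 11, k3 = 2, seed = 2L),
    ext_design(condition = "50 mM Mg", k1 = 11, k3 = 9, seed = 3L))
  panel <- gen_condition_panel(designs)
  expect_setequal(unique(panel$table$condition),
                  c("0 mM Mg", "2.5 mM Mg", "50 mM Mg"))
  expect_equal(names(panel$manifests),
               c("0 mM Mg", "2.5 mM Mg", "50 mM Mg"))

  # each condition independently fittable
  tc <- to_timecourse(panel$table, band_map("extension"))
  for (cond in names(panel$manifests)) {
    m <- panel$manifests[[cond]]
    f <- fit_k1(tc[tc$condition == cond, ], m$k2, m$k3, m$p_gly0)
    expect_lt(abs(f$k1 - m$k1) / m$k1, 1e-4)
  }

  one <- gen_condition_panel(designs[1])
  expect_identical(one$table$intensity,
                   gen_extension_experiment(designs[[1]])$table$intensity)
  expect_error(gen_condition_panel(list()), "nonempty")
  expect_error(gen_condition_panel(designs[c(1, 1)]), "duplicate")
})
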