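# Closed-form solutions of the three-species competing-pathway model,
# cross-checked against the numeric ODE oracle.

test_that("closed form reproduces the initial condition and simple limits", {
  r <- rate_constants(2, 1, 0.5)
  s0 <- eval_closed_form(r, initial_composition(0.6), 0)
  expect_equal(unlist(s0[, c("p_gly", "p_rna", "p_gly1", "p_rna1")]),
               c(p_gly = 0.6, p_rna = 0.4, p_gly1 = 0, p_rna1 = 0))

  # no hydrolysis, fully acylated: single-exponential conversion to NP+1
  t <- c(0.1, 0.5, 2)
  s <- eval_closed_form(rate_constants(12, 0, 5), 1, t)
  expect_equal(s$p_gly, exp(-12 * t))
  expect_equal(s$p_gly1, 1 - exp(-12 * t))
  expect_equal(s$p_rna, rep(0, 3))
  expect_equal(s$p_rna1, rep(0, 3))
})

test_that("closed form matches the frozen oracle-confirmed point", {
  # expected values computed with integrate_numeric (rtol 1e-10) and frozen
  s <- eval_closed_form(rate_constants(2, 1, 0.5), 0.6, 1)
  expect_equal(s$p_gly, 0.02987224, tolerance = 1e-6)
  expect_equal(s$p_rna, 0.37623072, tolerance = 1e-6)
  expect_equal(s$p_gly1, 0.38008519, tolerance = 1e-6)
  expect_equal(s$p_rna1, 0.21381185, tolerance = 1e-6)
})

test_that("numeric integration is trivial on degenerate inputs", {
  tr <- integrate_numeric(rate_constants(1, 2, 3), 0.7, 0)
  expect_equal(unlist(tr[1, -1]),
               c(p_gly = 0.7, p_rna = 0.3, p_gly1 = 0, p_rna1 = 0))

  tr0 <- integrate_numeric(rate_constants(0, 0, 0), 0.25, c(0.5, 1, 4))
  expect_equal(tr0$p_gly, rep(0.25, 3), tolerance = 1e-9)
  expect_equal(tr0$p_rna, rep(0.75, 3), tolerance = 1e-9)
})

test_that("closed form agrees with the numeric ODE oracle on random inputs", {
  set.seed(42)
  worst <- 0
  for (i in 1:100) {
    ks <- exp(stats::runif(3, log(0.01), log(50)))
    p0 <- stats::runif(1)
    tmax <- 5 / min(ks)
    times <- sort(stats::runif(6, 0, tmax))
    times <- times[c(TRUE, diff(times) > 1e-9)]
    r <- rate_constants(ks[1], ks[2], ks[3])
    cf <- simulate_trajectory(r, p0, times)
    nm <- integrate_numeric(r, p0, times)
    worst <- max(worst, max(abs(as.matrix(cf[, -1]) - as.matrix(nm[, -1]))))
  }
  expect_lt(worst, 1e-6)
})

test_that("fractions are conserved to 1e-9 for all valid inputs", {
  set.seed(7)
  for (i in 1:50) {
    ks <- exp(stats::runif(3, log(0.01), log(50)))
    p0 <- stats::runif(1)
    tr <- simulate_trajectory(rate_constants(ks[1], ks[2], ks[3]), p0,
                              seq(0, 5 / min(ks), length.out = 20))
    sums <- rowSums(tr[, c("p_gly", "p_rna", "p_gly1", "p_rna1")])
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("p_rna is continuous across the degenerate k3 = k1+k2 boundary", {
  k1 <- 1.2; k2 <- 0.8; K <- k1 + k2
  t <- c(0.3, 1, 2.5)
  eps <- 1e-7   # just outside the degenerate tolerance window
  below <- eval_closed_form(rate_constants(k1, k2, K * (1 - eps)), 0.5, t)
  exact <- eval_closed_form(rate_constants(k1, k2, K), 0.5, t)
  above <- eval_closed_form(rate_constants(k1, k2, K * (1 + eps)), 0.5, t)
  expect_equal(below$p_rna, exact$p_rna, tolerance = 1e-6)
  expect_equal(above$p_rna, exact$p_rna, tolerance = 1e-6)
})

test_that("trajectories are monotone where the model demands it", {
  set.seed(99)
  for (i in 1:20) {
    ks <- exp(stats::runif(3, log(0.05), log(20)))
    tr <- simulate_trajectory(rate_constants(ks[1], ks[2], ks[3]),
                              stats::runif(1), seq(0, 3, length.out = 40))
    expect_true(all(diff(tr$p_gly) <= 1e-12))
    expect_true(all(diff(tr$p_gly1) >= -1e-12))
    expect_true(all(diff(tr$p_gly1 + tr$p_rna1) >= -1e-12))
  }
})

test_that("branching yield gives the competing-pathway limit", {
  expect_equal(branching_yield(rate_constants(1, 0, 0), 1), 1)
  expect_equal(branching_yield(rate_constants(0, 1, 0.2), 0.5), 0)
  expect_equal(branching_yield(rate_constants(12, 0.7, 0), 0.5),
               0.5 * 12 / 12.7, tolerance = 1e-12)
  # agrees with the closed form at large t
  far <- eval_closed_form(rate_constants(12, 0.7, 0.1), 0.5, 100)
  expect_equal(branching_yield(rate_constants(12, 0.7, 0.1), 0.5),
               far$p_gly1, tolerance = 1e-9)
  expect_error(branching_yield(rate_constants(0, 0, 1), 0.5), "undefined")
})

test_that("invalid rates, compositions and times are rejected", {
  expect_error(rate_constants(-1, 0, 0), "k1")
  expect_error(rate_constants(1, Inf, 0), "k2")
  expect_error(initial_composition(1.2), "p_gly0")
  expect_error(eval_closed_form(rate_constants(1, 1, 1), 0.5, -0.1), "t")
  expect_error(simulate_trajectory(rate_constants(1, 1, 1), 0.5, c(1, 1)),
               "strictly increasing")
})
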