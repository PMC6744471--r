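test_that("average lifetime weighting", {
  expect_equal(average_lifetime(c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0)), 0.74)
  expect_equal(average_lifetime(c(0, 1, 0), c(0.2, 0.8, 2.0)), 0.8)
  expect_equal(average_lifetime(c(1, 1, 1), c(0.2, 0.8, 2.0)),
               mean(c(0.2, 0.8, 2.0)))
  # intensity weighting up-weights the slow components
  expect_gt(average_lifetime(c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0),
                             intensity_weighted = TRUE), 0.74)
  expect_error(average_lifetime(c(0, 0), c(1, 2)), "> 0")
})

test_that("convolution identities: delta IRF, zero amplitudes, area", {
  t_ns <- seq(0, 25, by = 0.05)
  d_irf <- delta_irf(t_ns)
  m <- convolve_decay(1, 1.0, 0, d_irf)
  expect_equal(m, exp(-t_ns), tolerance = 1e-12)
  expect_equal(convolve_decay(c(0, 0), c(1, 2), 3, d_irf),
               rep(3, length(t_ns)))
  # analytic area of sum A_k tau_k / dt, for grids spanning >> tau_max
  # and sampling finely relative to tau_min (point-sampled exponentials)
  tf <- seq(0, 25, by = 0.005)
  m3 <- convolve_decay(c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0), 0,
                       gaussian_irf(tf, 0.5, 0.05))
  analytic <- sum(c(0.5, 0.3, 0.2) * c(0.2, 0.8, 2.0)) / 0.005
  expect_equal(sum(m3), analytic, tolerance = 5e-3)
})

test_that("grid validation catches mismatches", {
  t_ns <- seq(0, 10, by = 0.1)
  irf <- delta_irf(t_ns)
  decay <- data.frame(t_ns = seq(0, 20, by = 0.1),
                      counts = exp(-seq(0, 20, by = 0.1)))
  expect_error(fit_decay(decay, irf), "grids do not match")
  expect_error(delta_irf(c(0, 1, 1.5)), "uniform")
})

test_that("single-exponential round trip through a delta IRF", {
  t_ns <- seq(0, 15, by = 0.02)
  irf <- delta_irf(t_ns)
  decay <- simulate_decay(1000, 1.5, irf)
  fit <- fit_decay(decay, irf, n_components = 1)
  expect_true(fit$converged)
  expect_equal(fit$lifetimes_ns, 1.5, tolerance = 1e-4)
  expect_equal(fit$tau_avg_ns, 1.5, tolerance = 1e-4)
})

test_that("triexponential reconvolution recovers the average lifetime", {
  t_ns <- seq(0, 20, by = 0.02)
  irf <- gaussian_irf(t_ns, t0_ns = 0.5, sigma_ns = 0.05)
  decay <- simulate_decay(1e4 * c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0), irf)
  fit <- fit_decay(decay, irf, n_components = 3)
  expect_true(fit$converged)
  expect_equal(fit$tau_avg_ns, 0.74, tolerance = 0.01)
  expect_true(all(diff(fit$lifetimes_ns) > 0))     # sorted ascending
})

test_that("lifetime recovery under Poisson counting noise", {
  t_ns <- seq(0, 20, by = 0.05)
  irf <- gaussian_irf(t_ns, 0.5, 0.1)
  errs <- vapply(1:10, function(s) {
    d <- simulate_decay(1e4 * c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0), irf,
                        baseline = 10, noise_model = "poisson", seed = s)
    f <- fit_decay(d, irf, n_components = 3)
    abs(f$tau_avg_ns - 0.74) / 0.74
  }, numeric(1))
  expect_lt(median(errs), 0.03)
})

test_that("three components do not fit worse than two on 2-component data", {
  t_ns <- seq(0, 20, by = 0.05)
  irf <- gaussian_irf(t_ns, 0.5, 0.1)
  d <- simulate_decay(1e4 * c(0.6, 0.4), c(0.5, 2.5), irf)
  f2 <- fit_decay(d, irf, n_components = 2)
  f3 <- fit_decay(d, irf, n_components = 3)
  expect_lt(f3$chi2_reduced, f2$chi2_reduced * 1.01 + 1e-9)
})

test_that("fitted lifetimes shorten monotonically with quenching", {
  # generator link: tau scales as 1/(1+NPQ)
  t_ns <- seq(0, 20, by = 0.05)
  irf <- gaussian_irf(t_ns, 0.5, 0.1)
  taus <- vapply(c(0, 0.5, 1.0, 1.5), function(q) {
    d <- simulate_decay(1e4 * c(0.5, 0.3, 0.2),
                        c(0.2, 0.8, 2.0) / (1 + q), irf)
    fit_decay(d, irf, n_components = 3)$tau_avg_ns
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("degenerate decay input is rejected", {
  t_ns <- seq(0, 10, by = 0.1)
  irf <- delta_irf(t_ns)
  expect_error(fit_decay(data.frame(t_ns = t_ns,
                                    counts = rep(0, length(t_ns))), irf),
               "all-zero")
  expect_error(fit_decay(data.frame(t_ns = t_ns[1:20],
                                    counts = rep(1, 20)),
                         delta_irf(t_ns[1:20])), "32")
})
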