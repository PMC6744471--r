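test_that("retention rules reproduce the six-point worked example", {
  out <- filter_points(filter_example_points())
  expect_equal(out$omit_reason,
               c("none", "none", "none", "none", "none", "high_irradiance"))
  expect_identical(out$retained, out$omit_reason == "none")
})

test_that("each omission rule fires with the right priority", {
  pts <- filter_example_points()
  pts$E <- rep(800, 6)
  expect_true(all(filter_points(pts)$omit_reason == "high_irradiance"))

  pts2 <- filter_example_points()
  pts2$y_npq[4] <- -0.02
  pts2$E[4] <- 800                     # negative Y(NPQ) outranks irradiance
  expect_equal(filter_points(pts2)$omit_reason[4], "negative_ynpq")

  # small sigma drop while Y(NPQ) rises
  pts3 <- data.frame(step_index = 1:4, E = c(50, 100, 200, 300),
                     sigma = c(500, 400, 399.5, 300),
                     y_npq = c(0, 0.1, 0.2, 0.3))
  out3 <- filter_points(pts3)
  expect_equal(out3$omit_reason, c("none", "none", "small_sigma_drop", "none"))
  # ... but not when Y(NPQ) did not rise
  pts3$y_npq <- c(0, 0.1, 0.1, 0.3)
  expect_true(all(filter_points(pts3)$retained))
})

test_that("the drop rule compares against the previous measured step", {
  # step 3 is omitted; step 4 must still be judged against step 3, not 2
  pts <- data.frame(step_index = 1:4, E = c(50, 100, 200, 300),
                    sigma = c(500, 400, 399, 350),
                    y_npq = c(0, 0.1, 0.2, 0.3))
  out <- filter_points(pts)
  expect_equal(out$omit_reason[3], "small_sigma_drop")
  expect_true(out$retained[4])         # 399 - 350 = 49 >= 5% of 150
})

test_that("filtering validates its input and flags degenerate curves", {
  pts <- filter_example_points()
  expect_error(filter_points(pts[c(2, 1, 3:6), ]), "ordered")
  pts$strain <- c("a", "a", "a", "b", "b", "b")
  expect_error(filter_points(pts), "mixed-curve")

  flat <- data.frame(step_index = 1:4, E = c(50, 100, 200, 300),
                     sigma = rep(500, 4), y_npq = c(0, 0.1, 0.2, 0.3))
  out <- filter_points(flat)
  expect_true(attr(out, "degenerate_total_decrease"))
  expect_equal(out$omit_reason[-1], rep("small_sigma_drop", 3))
  # filtering never adds points
  expect_equal(nrow(out), nrow(flat))
})

test_that("exact collinear points give a perfect regression", {
  pts <- data.frame(y_npq = c(0, 0.5, 1.0), sigma = c(500, 300, 100))
  r <- fit_sigma_ynpq(pts)
  expect_equal(r$slope, -400)
  expect_equal(r$intercept, 500)
  expect_equal(r$r2, 1)
  expect_equal(r$sigma_at_ynpq1, 100)
  expect_identical(r$sigma_at_ynpq1, r$intercept + r$slope)
  expect_lt(diff(r$ci95_slope), 1e-9)
  expect_lt(diff(r$ci95_intercept), 1e-9)
})

test_that("regression rejects degenerate designs", {
  expect_error(fit_sigma_ynpq(data.frame(y_npq = c(0, 0.5), sigma = 1:2)),
               ">= 3")
  expect_error(fit_sigma_ynpq(data.frame(y_npq = rep(0.3, 5),
                                         sigma = rnorm(5, 400))),
               "degenerate")
})

test_that("core cross-section arithmetic and linearity", {
  expect_equal(core_cross_section(9.8, 70, 893.5), 101.8, tolerance = 1e-3)
  expect_equal(core_cross_section(n_chl = 1), 1.454, tolerance = 1e-3)
  expect_equal(core_cross_section(n_chl = 140),
               2 * core_cross_section(n_chl = 70), tolerance = 1e-12)
  expect_equal(core_cross_section(a_star = 19.6),
               2 * core_cross_section(a_star = 9.8), tolerance = 1e-12)
  expect_equal(core_cross_section(m_chl = 2 * 893.5),
               2 * core_cross_section(), tolerance = 1e-12)
  expect_error(core_cross_section(a_star = 0), "> 0")
})

test_that("noise-free panel recovers the generative core exactly", {
  cfg <- two_acclimation_config(n_replicates = 1, noise = 0, qi_slope = 0)
  rep0 <- qe_report(compute_params(simulate_panel(cfg)))
  expect_equal(rep0$regression$sigma_at_ynpq1, 110, tolerance = 1e-6)
  expect_equal(rep0$regression$r2, 1, tolerance = 1e-9)
})

test_that("filtering moves the intercept toward the core when qI is present", {
  cfg <- two_acclimation_config(n_replicates = 2, noise = 0.02, seed = 21)
  rep1 <- qe_report(compute_params(simulate_panel(cfg)))
  unfiltered <- rep1$points
  unfiltered$retained <- TRUE
  reg_u <- fit_sigma_ynpq(unfiltered)
  expect_lt(abs(rep1$regression$sigma_at_ynpq1 - 110),
            abs(reg_u$sigma_at_ynpq1 - 110))
})

test_that("the 1-s-dark switch changes the sigma provenance", {
  cfg <- two_acclimation_config(n_replicates = 1, noise = 0.02, seed = 8)
  params <- compute_params(simulate_panel(cfg))
  a <- qe_report(params, one_second_dark = FALSE)
  b <- qe_report(params, one_second_dark = TRUE)
  expect_false(identical(a$regression$sigma_at_ynpq1,
                         b$regression$sigma_at_ynpq1))
  expect_equal(b$regression$sigma_at_ynpq1, 110, tolerance = 0.3 * 110)
})

test_that("an empty retained set is an actionable error", {
  params <- compute_params(
    simulate_light_curve(strain_spec("wt"), noise_rel_sd = 0))
  params$y_npq <- -abs(params$y_npq) - 0.01
  expect_error(qe_report(params), "no points retained")
})
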