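test_that("default panel encodes the strain qE ordering", {
  for (acc in c("LL", "HL")) {
    qe <- vapply(default_panel(acc), function(s) s$qe_ymax, numeric(1))
    expect_setequal(names(qe), c("wild-type", "x1KO", "x1KO+x2a", "x1KO+x3a",
                                 "x1KO+x4a", "x2KO", "x2KO+x2", "x2KO+x3"))
    expect_gt(qe[["x2KO+x2"]], qe[["wild-type"]])
    expect_equal(qe[["wild-type"]], qe[["x2KO"]])
    expect_gt(qe[["wild-type"]], qe[["x1KO+x3a"]])
    expect_gt(qe[["x1KO+x3a"]], qe[["x1KO+x2a"]])
    expect_gt(qe[["x1KO+x2a"]], qe[["x1KO"]])
    expect_equal(qe[["x1KO"]], qe[["x1KO+x4a"]])
    sd_dark <- vapply(default_panel(acc), function(s) s$sigma_dark,
                      numeric(1))
    expect_true(all(sd_dark >= 500 & sd_dark <= 550))
  }
  ll <- vapply(default_panel("LL"), function(s) s$qe_ymax, numeric(1))
  expect_identical(unname(ll[c("x1KO", "x1KO+x4a")]), c(0, 0))
  hl <- vapply(default_panel("HL"), function(s) s$qe_ymax, numeric(1))
  expect_true(all(hl > 0))
  expect_error(default_panel("ML"))
})

test_that("strain_spec enforces the no-Dt-no-qE invariant", {
  expect_equal(strain_spec("a", qe_ymax = 0.4, dt_capable = FALSE)$qe_ymax, 0)
  expect_equal(strain_spec("a", qe_ymax = 0.4, dtt_treated = TRUE)$qe_ymax, 0)
  expect_error(strain_spec("a", fo = 2, fm = 1), "fm > fo")
  expect_error(strain_spec("a", sigma_core = 600, sigma_dark = 525),
               "sigma_core")
  expect_error(strain_spec("a", qe_ymax = 1), "\\[0, 1\\)")
})

test_that("noise-free light curves keep fluorescence levels ordered", {
  for (s in default_panel("HL")) {
    cv <- simulate_light_curve(s, noise_rel_sd = 0)
    expect_true(all(cv$fo_prime <= cv$f_prime + 1e-12))
    expect_true(all(cv$f_prime <= cv$fm_prime + 1e-12))
    expect_true(all(cv$fm_prime <= s$fm + 1e-12))
  }
})

test_that("noisy light curves stay physically ordered and are reproducible", {
  s <- strain_spec("wt")
  a <- simulate_light_curve(s, noise_rel_sd = 0.05, seed = 9,
                            replicate_index = 2)
  b <- simulate_light_curve(s, noise_rel_sd = 0.05, seed = 9,
                            replicate_index = 2)
  expect_identical(a, b)
  c <- simulate_light_curve(s, noise_rel_sd = 0.05, seed = 9,
                            replicate_index = 3)
  expect_false(identical(a$f_prime, c$f_prime))
  expect_true(all(a$fo_prime <= a$f_prime & a$f_prime <= a$fm_prime))
})

test_that("sigma' declines linearly to the core value with saturating qE", {
  s <- strain_spec("s", qe_ymax = 0.6, sigma_dark = 525, sigma_core = 110)
  pr <- protocol_spec(step_irradiances = c(0, 100, 1e7))
  cv <- simulate_light_curve(s, pr, noise_rel_sd = 0)
  expect_equal(tail(cv$sigma_prime, 1), 525 - (525 - 110) * 0.6,
               tolerance = 1e-9)
})

test_that("generated (sigma', Y(NPQ)) pairs fall on the generative line", {
  for (s in default_panel("LL")) {
    s$qi_slope <- 0
    cv <- simulate_light_curve(s, noise_rel_sd = 0)
    p <- compute_params(cv)
    line <- s$sigma_dark - (s$sigma_dark - s$sigma_core) * p$y_npq
    expect_lt(max(abs(p$sigma_prime - line)), 1e-9)
  }
})

test_that("qE-less strains with connectivity show a sigma rise, qE strains a fall", {
  conn <- strain_spec("x1KO", qe_ymax = 0, kappa_conn = 0.08, qi_slope = 0)
  cv <- simulate_light_curve(conn, noise_rel_sd = 0)
  expect_true(all(diff(cv$sigma_prime) >= 0))
  expect_gt(tail(cv$sigma_prime, 1), conn$sigma_dark)

  wt <- strain_spec("wt", qe_ymax = 0.35, kappa_conn = 0)
  cv2 <- simulate_light_curve(wt, noise_rel_sd = 0)
  expect_true(all(diff(cv2$sigma_prime) <= 0))
})

test_that("DTT treatment is indistinguishable from a qE-less phenotype", {
  dtt <- strain_spec("wt", qe_ymax = 0.35, dtt_treated = TRUE)
  noqe <- strain_spec("wt", qe_ymax = 0, dtt_treated = FALSE)
  a <- simulate_light_curve(dtt, noise_rel_sd = 0.02, seed = 3)
  b <- simulate_light_curve(noqe, noise_rel_sd = 0.02, seed = 3)
  expect_equal(a$f_prime, b$f_prime, tolerance = 1e-14)
  expect_equal(a$sigma_prime, b$sigma_prime, tolerance = 1e-14)
})

test_that("simulated transient equals the model at zero noise and is seeded", {
  fl <- flash_spec()
  tr0 <- simulate_transient(1, 3, 500, 0, fl, noise_rel_sd = 0)
  expect_equal(tr0$signal, model_transient(1, 3, 500, 0, fl)$signal)
  expect_equal(tr0$signal[1], 1)
  a <- simulate_transient(1, 3, 500, 0, fl, noise_rel_sd = 0.02, seed = 5)
  b <- simulate_transient(1, 3, 500, 0, fl, noise_rel_sd = 0.02, seed = 5)
  expect_identical(a, b)
})

test_that("NPQ time course: qE induces and relaxes; qE-less lines are linear", {
  wt <- strain_spec("wt", qe_ymax = 0.35)
  tc <- simulate_npq_timecourse(wt)
  expect_equal(tc$npq[1], 0)
  hl <- tc[tc$phase == "HL", ]
  rec <- tc[tc$phase == "recovery", ]
  expect_true(all(diff(hl$npq) >= 0))
  expect_true(all(diff(rec$npq) <= 0))           # qE relaxes
  expect_gt(max(hl$npq), 0.3)

  ko <- strain_spec("x1KO", qe_ymax = 0)
  tk <- simulate_npq_timecourse(ko)
  hl_k <- tk[tk$phase == "HL", ]
  # pure linear accrual during HL, no relaxation afterwards
  expect_equal(diff(hl_k$npq), rep(diff(hl_k$npq)[1], nrow(hl_k) - 1),
               tolerance = 1e-12)
  expect_equal(diff(tk$npq[tk$phase == "recovery"]),
               rep(0, sum(tk$phase == "recovery") - 1), tolerance = 1e-12)

  # DTT-treated wild type behaves like the untreated qE-less line
  dtt <- strain_spec("x1KO", qe_ymax = 0.35, dtt_treated = TRUE)
  expect_equal(simulate_npq_timecourse(dtt)$npq, tk$npq, tolerance = 1e-14)
})

test_that("decay simulation respects convolution identities", {
  t_ns <- seq(0, 20, by = 0.05)
  d_irf <- delta_irf(t_ns)
  pure <- simulate_decay(c(1, 0, 0), c(1, 2, 3), d_irf)
  expect_equal(pure$counts, exp(-t_ns / 1), tolerance = 1e-12)
  flat <- simulate_decay(c(0, 0, 0), c(1, 2, 3), d_irf, baseline = 7)
  expect_equal(flat$counts, rep(7, length(t_ns)))
  # area preserved under a finite-width IRF
  g_irf <- gaussian_irf(t_ns, t0_ns = 0.5, sigma_ns = 0.1)
  a <- sum(simulate_decay(c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0), d_irf)$counts)
  b <- sum(simulate_decay(c(0.5, 0.3, 0.2), c(0.2, 0.8, 2.0), g_irf)$counts)
  expect_equal(b / a, 1, tolerance = 1e-3)
  # seeded Poisson noise is reproducible
  n1 <- simulate_decay(c(100, 0, 0), c(1, 2, 3), d_irf,
                       noise_model = "poisson", seed = 11)
  n2 <- simulate_decay(c(100, 0, 0), c(1, 2, 3), d_irf,
                       noise_model = "poisson", seed = 11)
  expect_identical(n1, n2)
})

test_that("panel simulation is deterministic for a fixed config", {
  cfg <- two_acclimation_config(n_replicates = 2, noise = 0.02, seed = 4)
  expect_identical(simulate_panel(cfg), simulate_panel(cfg))
  expect_error(panel_config(default_panel("LL"), n_replicates = 0), ">= 1")
  expect_error(panel_config(default_panel("LL"), noise_rel_sd = 0.6),
               "0.5")
})
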