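test_that("VW stress is zero at lambda = 1 and has slope E there, over random parameters", {
  set.seed(11)
  for (i in 1:25) {
    E <- 10^runif(1, 0, 4.5)
    gamma <- runif(1, 0, 8)
    expect_identical(vw_stress(1, E, gamma), 0)
    slope <- oracle_num_slope(function(l) vw_stress(l, E, gamma), 1)
    expect_equal(slope, E, tolerance = 1e-5)
  }
  # the spec-grid parameter pairs
  for (E in c(1, 1e4, 3e4)) {
    for (gamma in c(0, 2, 8)) {
      slope <- oracle_num_slope(function(l) vw_stress(l, E, gamma), 1)
      expect_equal(slope, E, tolerance = 1e-5)
    }
  }
})

test_that("VW stress matches direct scalar evaluation and is strictly increasing on [1, 1.2]", {
  expect_equal(vw_stress(1.2, E = 1, gamma = 0), 0.2359259, tolerance = 1e-6)
  lam <- seq(1, 1.2, length.out = 200)
  set.seed(12)
  for (i in 1:10) {
    E <- 10^runif(1, 0, 4); gamma <- runif(1, 0, 8)
    s <- vw_stress(lam, E, gamma)
    expect_equal(s, oracle_vw_scalar(lam, E, gamma))
    expect_true(all(diff(s) > 0))
  }
  expect_error(vw_stress(-0.1, 1, 1), "lambda")
  expect_error(vw_stress(1.1, 0, 1), "E")
  expect_error(vw_stress(1.1, 1, -1), "gamma")
})

test_that("CSA follows mass/(L0 x density) with unit conversion", {
  expect_equal(compute_csa(10, 10, 1.06), 0.01 / (1 * 1.06), tolerance = 1e-12)
  expect_equal(compute_csa(10, 10, 1.06), 9.434e-3, tolerance = 1e-4)
  expect_equal(compute_csa(20, 10), 2 * compute_csa(10, 10))
  expect_error(compute_csa(0, 10), "mass")
  expect_error(compute_csa(10, -1), "L0")
})

test_that("to_stress_strain recovers the generator grid and keeps only the loading ramp", {
  rec <- generate_stretch_recording(E_pa = 3e4, gamma = 4, mass_mg = 12,
                                    L0_mm = 9, noise_rel = 0, seed = 1)
  cur <- to_stress_strain(rec)
  gt <- rec$ground_truth
  expect_equal(cur$lambda, gt$lambda, tolerance = 1e-12)
  expect_equal(cur$sigma_pa, gt$sigma_pa, tolerance = 1e-9)
  expect_equal(cur$sigma_pa, cur$sigma_n_cm2 * 1e4)

  # appended unloading tail must be cut at the first lambda decrease
  rec2 <- stretch_recording(
    time_s = seq(0, 0.3, by = 0.1),
    length_mm = c(10, 10.5, 11, 10.8),
    force_mN = c(0, 1, 2, 1.5), L0_mm = 10, mass_mg = 10)
  cur2 <- to_stress_strain(rec2)
  expect_equal(cur2$n_points, 3L)
  expect_true(all(diff(cur2$lambda) >= 0))

  expect_error(stretch_recording(1:3, 1:2, 1:3, 10, 10), "equal length")
  # constant length at L0 with zero force: a flat curve at (1, 0)
  rec3 <- stretch_recording(0:4, rep(10, 5), rep(0, 5), 10, 10)
  cur3 <- to_stress_strain(rec3)
  expect_true(all(cur3$lambda == 1) && all(cur3$sigma_pa == 0))
})

test_that("VW fit recovers noiseless parameters to high precision and reports sane diagnostics", {
  for (par in list(c(3e4, 4), c(5e3, 0.5), c(1e4, 8))) {
    rec <- generate_stretch_recording(E_pa = par[1], gamma = par[2],
                                      mass_mg = 10, L0_mm = 10,
                                      noise_rel = 0, seed = 7)
    fit <- fit_veronda_westman(to_stress_strain(rec))
    expect_true(fit$converged)
    expect_equal(fit$E_pa, par[1], tolerance = 1e-6)
    expect_equal(fit$gamma, par[2], tolerance = 1e-6)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("VW fit handles the gamma = 0 boundary without destabilizing E", {
  rec <- generate_stretch_recording(E_pa = 2e4, gamma = 0, mass_mg = 10,
                                    L0_mm = 10, noise_rel = 0.02, seed = 21)
  fit <- fit_veronda_westman(to_stress_strain(rec))
  expect_true(fit$converged)
  expect_gte(fit$gamma, 0)
  expect_lt(abs(fit$E_pa - 2e4) / 2e4, 0.05)
})

test_that("VW fit estimates are unit-invariant up to the unit factor on E", {
  rec <- generate_stretch_recording(E_pa = 3e4, gamma = 4, mass_mg = 10,
                                    L0_mm = 10, noise_rel = 0.02, seed = 5)
  cur <- to_stress_strain(rec)
  fit_pa <- fit_veronda_westman(cur)
  cur_ncm2 <- cur
  cur_ncm2$sigma_pa <- cur$sigma_n_cm2  # refit on the N/cm^2 scale
  fit_ncm2 <- fit_veronda_westman(cur_ncm2)
  expect_equal(fit_ncm2$E_pa * 1e4, fit_pa$E_pa, tolerance = 1e-5)
  expect_equal(fit_ncm2$gamma, fit_pa$gamma, tolerance = 1e-5)
})

test_that("VW fit rejects degenerate or under-informative curves", {
  short <- list(lambda = seq(1, 1.2, length.out = 5),
                sigma_pa = rep(1, 5))
  expect_error(fit_veronda_westman(short), "10 points")
  narrow <- list(lambda = seq(1, 1.03, length.out = 50),
                 sigma_pa = seq(0, 1, length.out = 50))
  expect_error(fit_veronda_westman(narrow), "5%")
  flat <- list(lambda = rep(1, 50), sigma_pa = rep(0, 50))
  expect_error(fit_veronda_westman(flat))
})
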