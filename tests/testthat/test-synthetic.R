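test_that("stretch generator matches pointwise evaluation of the stress law and is seed-deterministic", {
  rec <- generate_stretch_recording(E_pa = 3e4, gamma = 4, mass_mg = 10,
                                    L0_mm = 10, noise_rel = 0, seed = 1)
  gt <- rec$ground_truth
  # independent per-point check: force = sigma * CSA, engineering units
  sigma <- oracle_vw_scalar(rec$length_mm / 10, 3e4, 4)
  expect_equal(rec$force_mN, (sigma / 1e4) * gt$csa_cm2 * 1000, tolerance = 1e-12)
  expect_identical(rec$force_mN[1], 0)  # sigma(1) = 0

  a <- generate_stretch_recording(E_pa = 3e4, gamma = 4, mass_mg = 10,
                                  L0_mm = 10, noise_rel = 0.02, seed = 42)
  b <- generate_stretch_recording(E_pa = 3e4, gamma = 4, mass_mg = 10,
                                  L0_mm = 10, noise_rel = 0.02, seed = 42)
  expect_identical(a, b)
  expect_error(generate_stretch_recording(3e4, 4, mass_mg = 0, L0_mm = 10,
                                          noise_rel = 0, seed = 1))
  expect_error(generate_stretch_recording(3e4, 4, mass_mg = 10, L0_mm = 10,
                                          noise_rel = 0))  # seed mandatory
})

test_that("generators never perturb the ambient RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(runif(1))
  invisible(generate_breath_log(seed = 5))
  invisible(generate_cohort(seed = 6))
  after <- runif(2)
  expect_identical(before, c(before[1], after))
})

test_that("OCE field generator plants delays of exactly dx / C and wraps phase correctly", {
  acq <- acquisition_config(displacement_noise_nm = 0)
  scene <- wave_scene(wave_speed_m_s = 2.5)
  f <- generate_oce_field(scene, acq, mode = "displacement", seed = 3)
  # peak times at two positions 400 um apart differ by 160 us = 10 frames
  i1 <- 1L; i2 <- 1L + 400 / acq$lateral_pixel_um
  p1 <- which.max(f$data[1, i1, ]); p2 <- which.max(f$data[1, i2, ])
  expect_equal((p2 - p1) * acq$frame_interval_s, 400e-6 / 2.5,
               tolerance = acq$frame_interval_s)

  # zero displacement <-> zero phase
  fz <- oce_field(array(0, c(2, 2, 20)), mode = "phase", acq = acq)
  expect_true(all(phase_to_displacement(fz)$data == 0))
  quiet <- generate_oce_field(wave_scene(pulse_amplitude_nm = 1e-9), acq,
                              mode = "phase", seed = 1)
  expect_lt(max(abs(quiet$data)), 1e-9)

  # phase mode wraps into (-pi, pi] and round-trips to < 1 nm noiseless
  fp <- generate_oce_field(scene, acq, mode = "phase", seed = 3)
  expect_true(max(fp$data) <= pi + 1e-12 && min(fp$data) > -pi - 1e-12)
  u <- phase_to_displacement(fp)
  expect_lt(max(abs(u$data - fp$ground_truth$displacement_clean_nm)), 1)

  # identical seeds give identical fields
  g1 <- generate_oce_field(scene, acquisition_config(), mode = "phase", seed = 8)
  g2 <- generate_oce_field(scene, acquisition_config(), mode = "phase", seed = 8)
  expect_identical(g1$data, g2$data)
})

test_that("OCE generator rejects windows too short for full pulse transit, naming the minimal n_frames", {
  acq <- acquisition_config(n_frames = 100, displacement_noise_nm = 0)
  err <- tryCatch(generate_oce_field(wave_scene(), acq, seed = 1),
                  error = function(e) conditionMessage(e))
  expect_match(err, "n_frames >= [0-9]+")
  n_min <- as.integer(sub(".*n_frames >= ([0-9]+).*", "\\1", err))
  acq_ok <- acquisition_config(n_frames = n_min, displacement_noise_nm = 0)
  expect_s3_class(generate_oce_field(wave_scene(), acq_ok, seed = 1), "oce_field")
})

test_that("breath log generator builds Mv = f * Tv and records planted outliers", {
  log <- generate_breath_log(profile = list(f = 400, Tv = 0.25, PIF = 7.6,
                                            PEF = 4.2, Ti = 0.057, Te = 0.129),
                             rel_sd = 0, mv_jitter = 0, seed = 4)
  expect_equal(log$Mv, rep(100, 60))
  log2 <- generate_breath_log(outlier_minutes = c(5, 17), seed = 9)
  expect_identical(attr(log2, "ground_truth")$outlier_minutes, c(5L, 17L))
  expect_error(generate_breath_log(outlier_minutes = 61, seed = 1),
               "out of range")
  expect_error(generate_breath_log(n_minutes = 2, seed = 1))
})

test_that("cohort generator hits its designed population R^2 and correlations at large n", {
  design <- cohort_design()
  tab <- generate_cohort(design, seed = 31, n_total = 10000)
  pop <- cohort_population(design)
  # empirical correlations with fibrosis converge to the design values
  for (v in c("alpha_tubulin", "beta_tubulin", "dt_tubulin",
              "transverse_stiffness", "longitudinal_stiffness", "peak_force")) {
    nm <- switch(v, alpha_tubulin = "alpha", beta_tubulin = "beta",
                 dt_tubulin = "dt", transverse_stiffness = "transverse",
                 longitudinal_stiffness = "longitudinal", peak_force = "force")
    expect_equal(cor(tab$fibrosis, tab[[v]]),
                 unname(pop$cor_with_fibrosis[nm]), tolerance = 0.02)
  }
  # simple-regression R^2 at large n matches the design target
  expect_equal(oracle_r2(tab["fibrosis"], tab$transverse_stiffness),
               design$r2_transverse, tolerance = 0.02)
  expect_equal(oracle_r2(tab["fibrosis"], tab$longitudinal_stiffness),
               design$r2_longitudinal, tolerance = 0.02)
  expect_equal(tab$dt_alpha_ratio, tab$dt_tubulin / tab$alpha_tubulin)
  expect_error(cohort_design(tubulin_cor = c(alpha = 1.2, beta = 0.5, dt = 0.5)),
               "positive semi-definite")
})

test_that("zero-noise unit-loading cohort is exactly linear in fibrosis", {
  design <- cohort_design(r2_transverse = 1, r2_longitudinal = 1, r2_force = 1)
  tab <- generate_cohort(design, seed = 1)
  fit <- fit_ols(tab, "transverse_stiffness", "fibrosis")
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-12)
})

test_that("filament image generator achieves the requested coverage and is deterministic", {
  st <- generate_filament_image(coverage = 0.20, seed = 13)
  expect_true(abs(st$ground_truth$coverage - 0.20) <= 0.005)
  expect_equal(mean(st$ground_truth$mask),
               st$ground_truth$coverage)  # stored mask is the ground truth
  st2 <- generate_filament_image(coverage = 0.20, seed = 13)
  expect_identical(st$frames, st2$frames)
  expect_error(generate_filament_image(coverage = 0, seed = 1), "strictly")
  expect_error(generate_filament_image(coverage = 1, seed = 1), "strictly")
})
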