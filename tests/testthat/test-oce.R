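make_pulse <- function(n = 128, center = 40, width = 6) {
  exp(-((seq_len(n) - center)^2) / (2 * width^2))
}

test_that("phase-to-displacement scaling matches the two-pass interferometric formula", {
  acq <- acquisition_config(n_depth = 1, n_lateral = 1, n_frames = 32,
                            displacement_noise_nm = 0)
  # a ramp reaching total phase 2*pi after unwrapping
  ph <- seq(0, 2 * pi, length.out = 32)
  wrapped <- pi - ((pi - ph) %% (2 * pi))
  f <- oce_field(array(wrapped, c(1, 1, 32)), mode = "phase", acq = acq)
  u <- phase_to_displacement(f)
  expect_equal(u$data[1, 1, 32], 840 / (2 * 1.38), tolerance = 1e-9)  # ~304.3 nm
  expect_false(any(attr(u, "flagged_traces")))
  expect_error(phase_to_displacement(u), "phase mode")
})

test_that("delay estimation is exact on integer shifts and matches the dense-lag oracle on fractional shifts", {
  dt <- 16e-6
  ref <- make_pulse()
  shifted3 <- make_pulse(center = 43)
  d <- estimate_delay(ref, shifted3, dt)
  expect_equal(d$delay_s, 3 * dt, tolerance = 1e-12)
  expect_equal(estimate_delay(ref, ref, dt)$delay_s, 0)
  expect_equal(estimate_delay(ref, ref, dt)$peak_corr, 1, tolerance = 1e-12)

  # fractional shifts: sub-frame resolution within 0.1 frame of truth and of
  # the brute-force oracle
  for (shift in c(0.5, 1.25, 2.5, 4.75)) {
    tr <- make_pulse(center = 40 + shift)
    est <- estimate_delay(ref, tr, dt)
    expect_lt(abs(est$delay_s - shift * dt), 0.1 * dt)
    orc <- oracle_dense_delay(ref, tr, dt)
    expect_lt(abs(est$delay_s - orc), 0.1 * dt)
  }
  expect_error(estimate_delay(rep(0, 64), ref[1:64], dt), "flat")
  expect_error(estimate_delay(ref, ref[-1], dt), "equal length")
  expect_error(estimate_delay(ref[1:8], make_pulse(n = 8), dt), "16 frames")
})

test_that("delay profile reproduces tau = (x - x0)/C and negates under reversed propagation", {
  acq <- acquisition_config(displacement_noise_nm = 0)
  f <- generate_oce_field(wave_scene(wave_speed_m_s = 2.5), acq,
                          mode = "displacement", seed = 2)
  p <- delay_profile(f, depth_index = 1, reference_x = 1)
  truth <- (p$x_um - p$x_um[1]) * 1e-6 / 2.5
  expect_lt(max(abs(p$delay_s - truth)), acq$frame_interval_s)  # one sub-frame
  expect_identical(p$delay_s[1], 0)
  expect_identical(p$peak_corr[1], 1)

  # reversed propagation: mirror the lateral axis; with the same reference
  # index the delays negate
  g <- f; g$data <- f$data[, rev(seq_len(dim(f$data)[2])), ]
  q <- delay_profile(g, depth_index = 1, reference_x = 1)
  expect_lt(max(abs(q$delay_s + p$delay_s)), 1e-8)
  expect_error(estimate_wave_speed(q), "slope")
})

test_that("wave-speed fit inverts an exact delay line and rejects non-physical profiles", {
  x_um <- seq(0, 630, by = 10)
  p <- data.frame(x_um = x_um, delay_s = x_um * 1e-6 / 2.5,
                  peak_corr = 1, edge = FALSE)
  attr(p, "depth_index") <- 1L
  class(p) <- c("delay_profile", "data.frame")
  est <- estimate_wave_speed(p)
  expect_equal(est$C_m_s, 2.5, tolerance = 1e-12)
  expect_equal(est$r_squared, 1, tolerance = 1e-12)

  flatp <- p; flatp$delay_s <- rep(1e-5, length(x_um))
  expect_error(estimate_wave_speed(flatp), "slope")
  few <- p[1:5, ]; few$peak_corr <- c(1, 1, 1, 0.2, 0.2)
  class(few) <- c("delay_profile", "data.frame")
  expect_error(estimate_wave_speed(few), "fewer than 4")
})

test_that("depth averaging uses only the superficial 0-100 um layer", {
  acq <- acquisition_config(displacement_noise_nm = 0)
  f <- generate_oce_field(wave_scene(wave_speed_m_s = 2.5), acq,
                          mode = "displacement", seed = 5)
  est <- depth_average_speed(f)
  one_row <- estimate_wave_speed(delay_profile(f, 5))
  expect_equal(est$C_m_s, one_row$C_m_s, tolerance = 0.01)  # homogeneous field
  expect_equal(est$n_rows, 21L)  # rows 0..100 um at 5 um pitch

  # two-layer field: C = 2 above 100 um, C = 4 below -> estimate sees the top
  top <- generate_oce_field(wave_scene(wave_speed_m_s = 2),
                            acquisition_config(n_depth = 21,
                                               displacement_noise_nm = 0),
                            mode = "displacement", seed = 6)
  bottom <- generate_oce_field(wave_scene(wave_speed_m_s = 4),
                               acquisition_config(n_depth = 19,
                                                  displacement_noise_nm = 0),
                               mode = "displacement", seed = 6)
  layered <- array(0, dim = c(40, 64, 320))
  layered[1:21, , ] <- top$data
  layered[22:40, , ] <- bottom$data
  two <- oce_field(layered, mode = "displacement", acq = acquisition_config())
  est2 <- depth_average_speed(two)
  expect_lt(abs(est2$C_m_s - 2) / 2, 0.03)

  # a field that is pure noise floor has no detectable surface
  silent <- oce_field(array(0.001, c(40, 64, 320)) *
                        array(stats::rnorm(40 * 64 * 320), c(40, 64, 320)),
                      mode = "displacement", acq = acquisition_config())
  expect_error(depth_average_speed(silent), "surface")
})

test_that("direction label never changes the numeric result", {
  acq <- acquisition_config()
  ft <- generate_oce_field(wave_scene(direction = "transverse"), acq,
                           mode = "phase", seed = 12)
  fl <- generate_oce_field(wave_scene(direction = "longitudinal"), acq,
                           mode = "phase", seed = 12)
  et <- depth_average_speed(phase_to_displacement(ft))
  el <- depth_average_speed(phase_to_displacement(fl))
  expect_identical(et$C_m_s, el$C_m_s)
})

test_that("surface-wave modulus obeys the closed form, scales as C^2 and validates inputs", {
  est <- surface_wave_modulus(2, rho = 1060, nu = 0.5)
  expect_equal(est$E_pa, 2 * 1060 * 1.5^3 * 4 / (0.87 + 1.12 * 0.5)^2)
  expect_equal(est$E_pa, 1.40e4, tolerance = 1e-3)
  set.seed(3)
  for (i in 1:20) {
    C <- runif(1, 0.5, 10); rho <- runif(1, 900, 1200); nu <- runif(1, 0.1, 0.5)
    e1 <- surface_wave_modulus(C, rho, nu)
    # the invariant holds exactly in the estimate's own fields
    expect_identical(e1$E_pa,
                     2 * e1$rho * (1 + e1$nu)^3 * e1$C_m_s^2 /
                       (0.87 + 1.12 * e1$nu)^2)
    expect_equal(surface_wave_modulus(2 * C, rho, nu)$E_pa, 4 * e1$E_pa,
                 tolerance = 1e-12)
  }
  expect_error(surface_wave_modulus(0), "C_m_s")
  expect_error(surface_wave_modulus(2, nu = 0.6), "nu")
  expect_error(surface_wave_modulus(2, nu = 0), "nu")
})

test_that("E is invariant under consistent rescaling of pixel pitch and frame data", {
  # the same physical wave sampled with 2x coarser lateral pixels at the
  # same frame rate keeps the same physical C, hence the same E
  acq1 <- acquisition_config(displacement_noise_nm = 0)
  f1 <- generate_oce_field(wave_scene(), acq1, mode = "displacement", seed = 4)
  acq2 <- acquisition_config(lateral_pixel_um = 20, n_lateral = 32,
                             displacement_noise_nm = 0)
  f2 <- generate_oce_field(wave_scene(), acq2, mode = "displacement", seed = 4)
  E1 <- surface_wave_modulus(depth_average_speed(f1))$E_pa
  E2 <- surface_wave_modulus(depth_average_speed(f2))$E_pa
  expect_equal(E1, E2, tolerance = 1e-3)
})
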