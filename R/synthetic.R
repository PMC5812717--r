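#' Passive-stretch protocol description
#'
#' Defaults mirror the study protocol: a ramp to 120% of optimal length
#' (20% strain) at 1 L0/s, sampled at 1 kHz.
#'
#' @param max_strain Peak engineering strain (dimensionless), > 0.
#' @param strain_rate Ramp rate in L0/s, > 0.
#' @param sample_rate Sampling rate (Hz).
#' @return A `stretch_protocol` list with the ramp `duration` (s) derived
#'   as `max_strain / strain_rate`.
#' @export
stretch_protocol <- function(max_strain = 0.20, strain_rate = 1.0,
                             sample_rate = 1000) {
  stopifnot_positive(max_strain, strain_rate, sample_rate,
                     .what = c("max_strain", "strain_rate", "sample_rate"))
  structure(list(max_strain = max_strain, strain_rate = strain_rate,
                 duration = max_strain / strain_rate,
                 sample_rate = sample_rate),
            class = "stretch_protocol")
}

#' Generate a synthetic passive-stretch recording
#'
#' Simulates a linear stretch ramp and evaluates the Veronda-Westman stress
#' at each sampled stretch, converting to force through the mass/L0 CSA
#' estimate. Noise is multiplicative (instrument-proportional), keeping the
#' signal-to-noise ratio uniform across the exponentially rising stress.
#'
#' @param E_pa True zero-strain Young's modulus (Pa).
#' @param gamma True stiffening rate (>= 0).
#' @param protocol A [stretch_protocol()].
#' @param mass_mg,L0_mm Strip wet mass (mg) and optimal length (mm).
#' @param noise_rel Relative SD of multiplicative force noise (default 0.02).
#' @param density_g_cm3 Muscle density for the CSA model.
#' @param seed Integer seed (mandatory).
#' @return A [stretch_recording()] whose `ground_truth` attribute records
#'   the true parameters and the noiseless (lambda, sigma) grid.
#' @export
generate_stretch_recording <- function(E_pa, gamma, protocol = stretch_protocol(),
                                       mass_mg, L0_mm, noise_rel = 0.02,
                                       density_g_cm3 = 1.06, seed) {
  stopifnot_positive(E_pa, mass_mg, L0_mm, .what = c("E_pa", "mass_mg", "L0_mm"))
  if (gamma < 0) stop("`gamma` must be >= 0.", call. = FALSE)
  if (noise_rel < 0) stop("`noise_rel` must be >= 0.", call. = FALSE)

  n <- max(2L, floor(protocol$duration * protocol$sample_rate) + 1L)
  time_s <- seq(0, protocol$duration, length.out = n)
  lambda <- 1 + protocol$strain_rate * time_s
  lambda <- pmin(lambda, 1 + protocol$max_strain)
  sigma_pa <- vw_stress(lambda, E_pa, gamma)
  csa <- compute_csa(mass_mg, L0_mm, density_g_cm3)
  force_mN <- (sigma_pa / 1e4) * csa * 1000

  eps <- with_seed(seed, stats::rnorm(n, mean = 0, sd = noise_rel))
  force_noisy <- if (noise_rel > 0) force_mN * (1 + eps) else force_mN

  stretch_recording(
    time_s = time_s, length_mm = lambda * L0_mm, force_mN = force_noisy,
    L0_mm = L0_mm, mass_mg = mass_mg,
    ground_truth = list(E_pa = E_pa, gamma = gamma, lambda = lambda,
                        sigma_pa = sigma_pa, csa_cm2 = csa,
                        noise_rel = noise_rel, seed = seed))
}

#' Elastic-wave scene for OCE simulation
#'
#' @param wave_speed_m_s True surface-wave propagation speed (m/s).
#' @param direction Fiber direction label, `"transverse"` or
#'   `"longitudinal"`. Purely a label: the simulation and all downstream
#'   processing are direction-agnostic.
#' @param pulse_center_s Arrival time of the pulse at the source (s).
#' @param pulse_width_s Full width (FWHM) of the Gaussian displacement
#'   pulse (s); default 1 ms, the duration scale of a focused air puff.
#' @param pulse_amplitude_nm Peak displacement (nm); micro-scale, default
#'   500 nm.
#' @param depth_decay_um Exponential decay length of amplitude with depth
#'   (um).
#' @param source_position_um Lateral position of the excitation (um).
#' @return A `wave_scene` list.
#' @export
wave_scene <- function(wave_speed_m_s = 2.5,
                       direction = c("transverse", "longitudinal"),
                       pulse_center_s = 1.5e-3, pulse_width_s = 1e-3,
                       pulse_amplitude_nm = 500, depth_decay_um = 150,
                       source_position_um = 0) {
  direction <- match.arg(direction)
  stopifnot_positive(wave_speed_m_s, pulse_width_s, pulse_amplitude_nm,
                     depth_decay_um,
                     .what = c("wave_speed_m_s", "pulse_width_s",
                               "pulse_amplitude_nm", "depth_decay_um"))
  structure(list(wave_speed_m_s = wave_speed_m_s, direction = direction,
                 pulse_center_s = pulse_center_s,
                 pulse_width_s = pulse_width_s,
                 pulse_amplitude_nm = pulse_amplitude_nm,
                 depth_decay_um = depth_decay_um,
                 source_position_um = source_position_um),
            class = "wave_scene")
}

#' OCE acquisition configuration
#'
#' Defaults follow the phase-sensitive OCT acquisition described for the
#' elastography system: 16 us frame interval, ~5 um axial pixel, ~11 nm
#' displacement noise. Center wavelength and tissue refractive index are
#' instrument constants that enter only the phase scale; they are carried
#' in the metadata of every field.
#'
#' @param frame_interval_s Time between frames (s); default 16e-6.
#' @param axial_pixel_um,lateral_pixel_um Pixel pitches (um).
#' @param n_depth,n_lateral,n_frames Array dimensions.
#' @param displacement_noise_nm Additive Gaussian displacement noise SD
#'   (nm); default 11.
#' @param wavelength_nm OCT center wavelength (nm); default 840.
#' @param refractive_index Tissue group refractive index; default 1.38.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(frame_interval_s = 16e-6, axial_pixel_um = 5,
                               lateral_pixel_um = 10, n_depth = 40,
                               n_lateral = 64, n_frames = 320,
                               displacement_noise_nm = 11,
                               wavelength_nm = 840, refractive_index = 1.38) {
  stopifnot_positive(frame_interval_s, axial_pixel_um, lateral_pixel_um,
                     n_depth, n_lateral, n_frames, wavelength_nm,
                     refractive_index,
                     .what = c("frame_interval_s", "axial_pixel_um",
                               "lateral_pixel_um", "n_depth", "n_lateral",
                               "n_frames", "wavelength_nm", "refractive_index"))
  if (displacement_noise_nm < 0) {
    stop("`displacement_noise_nm` must be >= 0.", call. = FALSE)
  }
  structure(list(frame_interval_s = frame_interval_s,
                 axial_pixel_um = axial_pixel_um,
                 lateral_pixel_um = lateral_pixel_um,
                 n_depth = as.integer(n_depth),
                 n_lateral = as.integer(n_lateral),
                 n_frames = as.integer(n_frames),
                 displacement_noise_nm = displacement_noise_nm,
                 wavelength_nm = wavelength_nm,
                 refractive_index = refractive_index),
            class = "acquisition_config")
}

#' Generate a synthetic OCE spatiotemporal field
#'
#' Builds a depth x lateral x time displacement field for a laterally
#' propagating, depth-attenuating Gaussian pulse,
#' \deqn{u(z, x, t) = A e^{-z/d}\, g\!\left(t - \frac{x - x_0}{C}\right),}
#' adds Gaussian displacement noise, and emits the field either as
#' displacement (nm) or as wrapped two-pass interferometric phase
#' \eqn{\phi = 4\pi n u / \lambda_0} with each value in (-pi, pi].
#'
#' @param scene A [wave_scene()].
#' @param acq An [acquisition_config()].
#' @param mode `"displacement"` or `"phase"` output.
#' @param seed Integer seed (mandatory).
#' @return An [oce_field()] carrying the acquisition metadata and a
#'   `ground_truth` attribute (true speed, noiseless displacement).
#' @export
generate_oce_field <- function(scene, acq = acquisition_config(),
                               mode = c("displacement", "phase"), seed) {
  mode <- match.arg(mode)
  stopifnot(inherits(scene, "wave_scene"), inherits(acq, "acquisition_config"))

  t <- (seq_len(acq$n_frames) - 1L) * acq$frame_interval_s
  x_um <- (seq_len(acq$n_lateral) - 1L) * acq$lateral_pixel_um
  z_um <- (seq_len(acq$n_depth) - 1L) * acq$axial_pixel_um

  sigma_t <- scene$pulse_width_s / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  # arrival time at the farthest lateral position from the source
  max_dist_m <- max(abs(x_um - scene$source_position_um)) * 1e-6
  t_last <- scene$pulse_center_s + max_dist_m / scene$wave_speed_m_s + 3 * sigma_t
  if (t_last > max(t)) {
    n_min <- ceiling(t_last / acq$frame_interval_s) + 1L
    stop(sprintf(
      "pulse exits the time window: need n_frames >= %d (have %d) for full transit.",
      n_min, acq$n_frames), call. = FALSE)
  }

  arrival <- scene$pulse_center_s +
    (x_um - scene$source_position_um) * 1e-6 / scene$wave_speed_m_s
  # pulse(t) per lateral position: n_lateral x n_frames
  pulse_xt <- exp(-outer(arrival, t, function(a, tt) (tt - a)^2) / (2 * sigma_t^2))
  decay_z <- exp(-z_um / scene$depth_decay_um)
  u <- scene$pulse_amplitude_nm *
    outer(decay_z, pulse_xt)  # n_depth x n_lateral x n_frames
  dim(u) <- c(acq$n_depth, acq$n_lateral, acq$n_frames)
  u_clean <- u

  if (acq$displacement_noise_nm > 0) {
    noise <- with_seed(seed, stats::rnorm(length(u), 0, acq$displacement_noise_nm))
    u <- u + array(noise, dim = dim(u))
  }

  data <- if (mode == "phase") {
    wrap_phase(4 * pi * acq$refractive_index * u / acq$wavelength_nm)
  } else {
    u
  }
  oce_field(data, mode = mode, acq = acq, direction = scene$direction,
            ground_truth = list(wave_speed_m_s = scene$wave_speed_m_s,
                                displacement_clean_nm = u_clean,
                                scene = scene, seed = seed))
}

#' Generate a synthetic minute-resolution plethysmography log
#'
#' Emits one row per minute with breath frequency `f`, tidal volume `Tv`,
#' minute ventilation `Mv`, peak flows and breath timings. `Mv` is built as
#' `f * Tv * (1 + jitter)`, mirroring how minute ventilation relates to its
#' factors. Planted outlier minutes have `f` displaced by
#' `outlier_shift_sd` nominal SDs (default 20: a breath-hold or burrowing
#' excursion moves frequency by hundreds of breaths/min, far beyond the
#' few-breaths/min minute-to-minute jitter), alternating in sign.
#'
#' @param profile Named list of nominal means; defaults follow a healthy
#'   wild-type mouse: `f` 408 breaths/min, `Tv` 0.25 ml, `PIF` 7.6 ml/s,
#'   `PEF` 4.2 ml/s, `Ti` 0.057 s, `Te` 0.129 s.
#' @param n_minutes Number of rows (default 60).
#' @param outlier_minutes Integer minute indices (1-based) to displace.
#' @param rel_sd Relative minute-to-minute SD of each variable (default 0.02).
#' @param mv_jitter Relative SD of the multiplicative jitter on
#'   `Mv = f * Tv` (default 0.01, <= 2%).
#' @param outlier_shift_sd Displacement of outlier `f`, in units of the
#'   nominal SD `rel_sd * f`.
#' @param seed Integer seed (mandatory).
#' @return A `breath_log` data.frame (columns `minute`, `f`, `Tv`, `Mv`,
#'   `PIF`, `PEF`, `Ti`, `Te`) with the planted outlier set in
#'   `attr(, "ground_truth")`.
#' @export
generate_breath_log <- function(profile = list(f = 408, Tv = 0.25, PIF = 7.6,
                                               PEF = 4.2, Ti = 0.057, Te = 0.129),
                                n_minutes = 60, outlier_minutes = integer(),
                                rel_sd = 0.02, mv_jitter = 0.01,
                                outlier_shift_sd = 20, seed) {
  if (n_minutes < 3) stop("`n_minutes` must be >= 3.", call. = FALSE)
  if (mv_jitter < 0 || mv_jitter > 0.02) {
    stop("`mv_jitter` must be in [0, 0.02].", call. = FALSE)
  }
  outlier_minutes <- as.integer(outlier_minutes)
  if (length(outlier_minutes) &&
      (any(outlier_minutes < 1) || any(outlier_minutes > n_minutes))) {
    stop("outlier minute index out of range.", call. = FALSE)
  }

  log <- with_seed(seed, {
    draw <- function(mu) mu * (1 + stats::rnorm(n_minutes, 0, rel_sd))
    f <- draw(profile$f); Tv <- draw(profile$Tv)
    if (length(outlier_minutes)) {
      shift <- outlier_shift_sd * rel_sd * profile$f *
        rep_len(c(1, -1), length(outlier_minutes))
      f[outlier_minutes] <- f[outlier_minutes] + shift
    }
    Mv <- f * Tv * (1 + stats::rnorm(n_minutes, 0, mv_jitter))
    data.frame(minute = seq_len(n_minutes), f = f, Tv = Tv, Mv = Mv,
               PIF = draw(profile$PIF), PEF = draw(profile$PEF),
               Ti = draw(profile$Ti), Te = draw(profile$Te))
  })
  attr(log, "ground_truth") <- list(outlier_minutes = sort(outlier_minutes),
                                    profile = profile, rel_sd = rel_sd,
                                    seed = seed)
  class(log) <- c("breath_log", "data.frame")
  log
}

#' Cohort design for the stiffness-determinant simulation
#'
#' Describes a synthetic animal cohort in which interstitial fibrosis is the
#' latent driver of tissue stiffness and force, while tubulin measures
#' correlate with fibrosis without adding independent signal — the structure
#' under which fibrosis alone should capture (almost) all explainable
#' variance in a multiple regression.
#'
#' Loadings are expressed as target population R-squared values of the
#' simple regression of each response on fibrosis: the generator converts
#' them to residual noise SDs analytically, so the design values are
#' recoverable by the regression stage. Defaults follow the study's
#' variance-partition pattern: fibrosis explains ~0.70 of transverse
#' stiffness, ~0.45 of longitudinal stiffness and ~0.57 of peak force, with
#' three groups of eight animals (healthy, dystrophic, rescued dystrophic).
#'
#' @param n_per_group Animals per group.
#' @param groups Group labels.
#' @param fibrosis_mean Per-group mean fibrosis fraction.
#' @param fibrosis_sd Within-group fibrosis SD.
#' @param r2_transverse,r2_longitudinal,r2_force Target population
#'   R-squared of fibrosis on each response, each in (0, 1].
#' @param stiffness_scale_kpa Stiffness produced per unit fibrosis (kPa);
#'   sets the slope linking fibrosis to transverse stiffness (the
#'   longitudinal slope is 40% of it, reflecting anisotropy).
#' @param force_scale Peak-force change per unit fibrosis (N/cm^2,
#'   negative: fibrotic tissue is weaker).
#' @param tubulin_cor Named vector of population correlations between
#'   fibrosis and `alpha`, `beta`, `dt` tubulin (each in [-1, 1]).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_per_group = 8,
                          groups = c("WT", "mdx", "p47-mdx"),
                          fibrosis_mean = c(0.05, 0.22, 0.12),
                          fibrosis_sd = 0.035,
                          r2_transverse = 0.70, r2_longitudinal = 0.45,
                          r2_force = 0.57,
                          stiffness_scale_kpa = 60,
                          force_scale = -45,
                          tubulin_cor = c(alpha = 0.68, beta = 0.71, dt = 0.72)) {
  if (length(fibrosis_mean) != length(groups)) {
    stop("`fibrosis_mean` must have one value per group.", call. = FALSE)
  }
  stopifnot_positive(n_per_group, fibrosis_sd,
                     .what = c("n_per_group", "fibrosis_sd"))
  for (r2 in c(r2_transverse, r2_longitudinal, r2_force)) {
    if (r2 <= 0 || r2 > 1) stop("target R^2 values must lie in (0, 1].", call. = FALSE)
  }
  if (any(abs(tubulin_cor) > 1)) {
    stop("tubulin-fibrosis correlations must lie in [-1, 1] ",
         "(implied covariance otherwise not positive semi-definite).", call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group), groups = groups,
                 fibrosis_mean = fibrosis_mean, fibrosis_sd = fibrosis_sd,
                 r2_transverse = r2_transverse,
                 r2_longitudinal = r2_longitudinal, r2_force = r2_force,
                 stiffness_scale_kpa = stiffness_scale_kpa,
                 force_scale = force_scale, tubulin_cor = tubulin_cor),
            class = "cohort_design")
}

#' Population moments and correlations implied by a cohort design
#'
#' The pooled fibrosis distribution is a balanced mixture of within-group
#' normals, so its variance is the within-group variance plus the variance
#' of the group means. Simple-regression population R-squared of a response
#' generated as `slope * fibrosis + noise` is
#' `slope^2 var(f) / (slope^2 var(f) + sd_noise^2)`; tubulin columns are
#' generated at exact population correlation with fibrosis.
#'
#' @param design A [cohort_design()].
#' @return List with pooled fibrosis `mean` and `var`, per-response noise
#'   SDs, and the implied fibrosis-column correlation vector.
#' @export
cohort_population <- function(design) {
  m <- design$fibrosis_mean
  var_f <- design$fibrosis_sd^2 + mean((m - mean(m))^2)
  noise_sd_for <- function(slope, r2) {
    # r2 = s^2 v / (s^2 v + n^2)  =>  n = |s| sqrt(v (1 - r2) / r2)
    abs(slope) * sqrt(var_f * (1 - r2) / r2)
  }
  slope_trans <- design$stiffness_scale_kpa
  slope_long <- 0.4 * design$stiffness_scale_kpa
  slope_force <- design$force_scale
  list(fibrosis_mean = mean(m), fibrosis_var = var_f,
       slopes = c(transverse = slope_trans, longitudinal = slope_long,
                  force = slope_force),
       noise_sd = c(transverse = noise_sd_for(slope_trans, design$r2_transverse),
                    longitudinal = noise_sd_for(slope_long, design$r2_longitudinal),
                    force = noise_sd_for(slope_force, design$r2_force)),
       cor_with_fibrosis = c(alpha = unname(design$tubulin_cor[["alpha"]]),
                             beta = unname(design$tubulin_cor[["beta"]]),
                             dt = unname(design$tubulin_cor[["dt"]]),
                             transverse = sqrt(design$r2_transverse),
                             longitudinal = sqrt(design$r2_longitudinal),
                             force = -sqrt(design$r2_force)))
}

#' Generate a synthetic animal cohort table
#'
#' Draws per-animal fibrosis from the design's group means, then generates
#' stiffness and force responses as linear functions of fibrosis plus noise
#' calibrated to the design's population R-squared targets, and tubulin
#' densitometry columns at the design's population correlation with
#' fibrosis. The de-tyrosinated/alpha tubulin ratio is the quotient of the
#' generated columns. Tubulin columns carry no signal about stiffness
#' beyond their correlation with fibrosis.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed (mandatory).
#' @param n_total Optional override of total cohort size (rounded up to a
#'   multiple of the number of groups); used for large-n convergence checks.
#' @return A `cohort_table` data.frame with columns `group`, `fibrosis`,
#'   `alpha_tubulin`, `beta_tubulin`, `dt_tubulin`, `dt_alpha_ratio`,
#'   `transverse_stiffness`, `longitudinal_stiffness`, `peak_force`;
#'   design and population moments stored in `attr(, "ground_truth")`.
#' @export
generate_cohort <- function(design = cohort_design(), seed, n_total = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  g <- length(design$groups)
  npg <- if (is.null(n_total)) design$n_per_group else as.integer(ceiling(n_total / g))
  n <- npg * g
  pop <- cohort_population(design)

  tab <- with_seed(seed, {
    group <- rep(design$groups, each = npg)
    fib <- stats::rnorm(n, rep(design$fibrosis_mean, each = npg),
                        design$fibrosis_sd)
    zf <- (fib - pop$fibrosis_mean) / sqrt(pop$fibrosis_var)
    tub <- function(r, mu, sd) {
      mu * (1 + sd * (r * zf + sqrt(1 - r^2) * stats::rnorm(n)))
    }
    alpha <- tub(design$tubulin_cor[["alpha"]], 1.0, 0.30)
    beta <- tub(design$tubulin_cor[["beta"]], 1.0, 0.30)
    dt <- tub(design$tubulin_cor[["dt"]], 1.0, 0.35)
    data.frame(
      group = group, fibrosis = fib,
      alpha_tubulin = alpha, beta_tubulin = beta, dt_tubulin = dt,
      dt_alpha_ratio = dt / alpha,
      transverse_stiffness = 3 + pop$slopes[["transverse"]] * fib +
        stats::rnorm(n, 0, pop$noise_sd[["transverse"]]),
      longitudinal_stiffness = 2 + pop$slopes[["longitudinal"]] * fib +
        stats::rnorm(n, 0, pop$noise_sd[["longitudinal"]]),
      peak_force = 22 + pop$slopes[["force"]] * fib +
        stats::rnorm(n, 0, pop$noise_sd[["force"]]))
  })
  attr(tab, "ground_truth") <- list(design = design, population = pop, seed = seed)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' Generate a synthetic filament-texture image stack
#'
#' Emulates a fluorescence stack of randomly oriented bright line segments
#' (filament texture) over a dark background, with a known total foreground
#' coverage. Segments are accumulated until the union mask's pixel fraction
#' reaches `coverage` within +/- 0.5% absolute; each segment is assigned to
#' a random frame of the stack so that only the summed stack shows the full
#' texture.
#'
#' @param coverage Target foreground pixel fraction, strictly in (0, 1).
#' @param n_frames Number of frames (default 10).
#' @param size Image side length in pixels (square frames).
#' @param fg_intensity,bg_intensity Mean foreground/background intensity in
#'   [0, 1] (16-bit scale on export).
#' @param noise_sd Additive Gaussian intensity noise SD (0 = noiseless).
#' @param seg_len Segment length in pixels.
#' @param seed Integer seed (mandatory).
#' @return An `image_stack` list: `frames` (size x size x n_frames array),
#'   `pixel_um`, and `ground_truth` holding the union `mask` and achieved
#'   `coverage`.
#' @export
generate_filament_image <- function(coverage, n_frames = 10, size = 256,
                                    fg_intensity = 0.85, bg_intensity = 0.05,
                                    noise_sd = 0, seg_len = 24, seed) {
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must lie strictly in (0, 1).", call. = FALSE)
  }
  stopifnot_positive(n_frames, size, seg_len, .what = c("n_frames", "size", "seg_len"))

  out <- with_seed(seed, {
    mask <- matrix(FALSE, size, size)
    total <- size * size
    target <- coverage * total
    frame_of <- integer(0)
    seg_pixels <- list()
    max_iter <- ceiling(4 * target / seg_len) + 1000L
    iter <- 0L
    while (sum(mask) < target - 0.0025 * total && iter < max_iter) {
      iter <- iter + 1L
      x0 <- stats::runif(1, 1, size); y0 <- stats::runif(1, 1, size)
      th <- stats::runif(1, 0, pi)
      tt <- seq(0, seg_len, by = 0.5)
      xs <- round(x0 + tt * cos(th)); ys <- round(y0 + tt * sin(th))
      ok <- xs >= 1 & xs <= size & ys >= 1 & ys <= size
      if (!any(ok)) next
      idx <- unique(cbind(xs[ok], ys[ok]))
      # stop before overshooting the +0.5% band
      new <- idx[!mask[idx], , drop = FALSE]
      if (sum(mask) + nrow(new) > target + 0.0025 * total) {
        keep <- max(0L, floor(target + 0.0025 * total) - sum(mask))
        if (keep <= 0L) break
        new <- new[seq_len(min(keep, nrow(new))), , drop = FALSE]
      }
      if (!nrow(new)) next
      mask[new] <- TRUE
      seg_pixels[[length(seg_pixels) + 1L]] <- new
      frame_of <- c(frame_of, sample.int(n_frames, 1L))
    }
    achieved <- sum(mask) / total
    if (abs(achieved - coverage) > 0.005) {
      stop(sprintf(
        "coverage %.3f unreachable for size %d (achieved %.3f); increase size or segment budget.",
        coverage, size, achieved), call. = FALSE)
    }
    frames <- array(bg_intensity, dim = c(size, size, n_frames))
    for (k in seq_along(seg_pixels)) {
      px <- seg_pixels[[k]]
      f <- frame_of[k]
      frames[cbind(px, f)] <- fg_intensity
    }
    if (noise_sd > 0) {
      frames <- frames + array(stats::rnorm(length(frames), 0, noise_sd),
                               dim = dim(frames))
      frames <- pmin(pmax(frames, 0), 1)
    }
    list(frames = frames, mask = mask, achieved = achieved)
  })

  structure(list(frames = out$frames, pixel_um = 0.1,
                 ground_truth = list(mask = out$mask,
                                     coverage = out$achieved,
                                     target_coverage = coverage, seed = seed)),
            class = "image_stack")
}
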