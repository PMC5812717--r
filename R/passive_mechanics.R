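#' Veronda-Westman uniaxial stress
#'
#' Engineering axial stress of an incompressible Veronda-Westman material
#' under uniaxial tension,
#' \deqn{\sigma(\lambda) = \frac{2E}{3}\left(\lambda^2 - \frac{1}{\lambda}\right)
#'   \left(e^{\gamma(\lambda^2 + 2/\lambda - 3)} - \frac{1}{2\lambda}\right),}
#' where \eqn{\lambda = 1 + \epsilon} is the stretch ratio, `E` is the
#' Young's modulus at zero strain and `gamma` the exponential stiffening
#' rate. The law satisfies \eqn{\sigma(1) = 0} and
#' \eqn{d\sigma/d\lambda|_{\lambda=1} = E} for every admissible parameter
#' pair, which is what makes `E` interpretable as a zero-strain modulus.
#'
#' @param lambda Stretch ratio(s), \eqn{\lambda \ge 1} on a loading ramp.
#'   Values \eqn{\le 0} are rejected; mild unloading values in (0, 1) are
#'   evaluated but not meaningful for the loading-ramp fit.
#' @param E Zero-strain Young's modulus (Pa), > 0.
#' @param gamma Dimensionless stiffening rate, >= 0.
#' @return Stress in the units of `E` (Pa if `E` is Pa), same shape as
#'   `lambda`.
#' @export
#' @examples
#' vw_stress(1.2, E = 1, gamma = 0) # ~0.2359
vw_stress <- function(lambda, E, gamma) {
  stopifnot_positive(E, .what = "E")
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) || gamma < 0) {
    stop("`gamma` must be a single finite number >= 0.", call. = FALSE)
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be positive and finite.", call. = FALSE)
  }
  (2 * E / 3) * (lambda^2 - 1 / lambda) *
    (exp(gamma * (lambda^2 + 2 / lambda - 3)) - 1 / (2 * lambda))
}

#' Estimated cross-sectional area of a muscle strip
#'
#' Physiological CSA from wet mass and optimal length,
#' CSA = mass / (L0 x density), used to normalize both passive force
#' (stress) and tetanic force (specific force, N/cm^2).
#'
#' @param mass_mg Muscle wet mass (mg).
#' @param L0_mm Optimal length L0 (mm).
#' @param density_g_cm3 Muscle density (g/cm^3); default 1.06.
#' @return CSA in cm^2.
#' @export
#' @examples
#' compute_csa(10, 10) # ~9.434e-3 cm^2
compute_csa <- function(mass_mg, L0_mm, density_g_cm3 = 1.06) {
  stopifnot_positive(mass_mg, L0_mm, density_g_cm3,
                     .what = c("mass_mg", "L0_mm", "density_g_cm3"))
  (mass_mg / 1000) / ((L0_mm / 10) * density_g_cm3)
}

#' Construct a passive-stretch recording object
#'
#' @param time_s,length_mm,force_mN Equal-length numeric vectors: sample
#'   times (s), instantaneous strip length (mm) and passive force (mN).
#' @param L0_mm Optimal length (mm).
#' @param mass_mg Wet mass (mg).
#' @param ground_truth Optional list of generator ground truth (kept as an
#'   attribute; never used by the fitting code).
#' @return A `stretch_recording` object.
#' @export
stretch_recording <- function(time_s, length_mm, force_mN, L0_mm, mass_mg,
                              ground_truth = NULL) {
  n <- length(time_s)
  if (length(length_mm) != n || length(force_mN) != n) {
    stop("`time_s`, `length_mm` and `force_mN` must have equal length.",
         call. = FALSE)
  }
  stopifnot_positive(L0_mm, mass_mg, .what = c("L0_mm", "mass_mg"))
  structure(
    list(time_s = as.numeric(time_s), length_mm = as.numeric(length_mm),
         force_mN = as.numeric(force_mN), L0_mm = L0_mm, mass_mg = mass_mg,
         ground_truth = ground_truth),
    class = "stretch_recording")
}

#' Convert a stretch recording to a stress-strain curve
#'
#' Computes stretch \eqn{\lambda_i = length_i / L_0} and engineering stress
#' \eqn{\sigma_i = F_i / CSA}, then keeps only the first loading ramp,
#' operationalized as the longest initial monotone non-decreasing segment
#' of \eqn{\lambda}. Stress is reported both in N/cm^2 (the reporting
#' convention for muscle) and Pa.
#'
#' @param rec A [stretch_recording()].
#' @param density_g_cm3 Muscle density used for the CSA estimate.
#' @return A `stress_strain_curve`: list with `lambda`, `strain`,
#'   `sigma_n_cm2`, `sigma_pa`, `csa_cm2`, `n_points`.
#' @export
to_stress_strain <- function(rec, density_g_cm3 = 1.06) {
  stopifnot(inherits(rec, "stretch_recording"))
  csa <- compute_csa(rec$mass_mg, rec$L0_mm, density_g_cm3)
  lambda <- rec$length_mm / rec$L0_mm
  # first loading ramp: longest initial non-decreasing prefix of lambda
  n <- length(lambda)
  end <- n
  if (n > 1L) {
    drops <- which(diff(lambda) < 0)
    if (length(drops)) end <- drops[1L]
  }
  if (end < 1L) stop("no monotone loading segment found", call. = FALSE)
  idx <- seq_len(end)
  sigma_n_cm2 <- (rec$force_mN[idx] / 1000) / csa
  structure(
    list(lambda = lambda[idx], strain = lambda[idx] - 1,
         sigma_n_cm2 = sigma_n_cm2, sigma_pa = sigma_n_cm2 * 1e4,
         csa_cm2 = csa, n_points = end),
    class = "stress_strain_curve")
}

#' Fit the Veronda-Westman model to a stress-strain curve
#'
#' Unweighted nonlinear least squares of [vw_stress()] against the measured
#' engineering stress, estimating the zero-strain Young's modulus `E` (Pa)
#' and stiffening rate `gamma`. Initialization uses the model-consistent
#' small-strain secant slope for `E` (stress over the first 2% strain) and
#' `gamma = 1`; bounds are `E > 0`, `gamma` in [0, 50] to preclude
#' exponential overflow.
#'
#' @param curve A `stress_strain_curve` from [to_stress_strain()], or any
#'   list with `lambda` and `sigma_pa`.
#' @param gamma_max Upper bound on gamma (default 50).
#' @return A `vw_fit` list: `E_pa`, `gamma`, `se` (named standard errors
#'   from the Jacobian at the optimum), `rss`, `r_squared`, `n_points`,
#'   `converged`. Parameter fields are `NA` when the optimizer fails to
#'   converge.
#' @export
fit_veronda_westman <- function(curve, gamma_max = 50) {
  lambda <- curve$lambda
  sigma <- curve$sigma_pa
  if (length(lambda) < 10L) {
    stop("need at least 10 points to fit the two-parameter model.", call. = FALSE)
  }
  if (max(lambda) - 1 < 0.05) {
    stop("curve must span at least 5% strain.", call. = FALSE)
  }
  if (diff(range(lambda)) < .Machine$double.eps^0.5) {
    stop("degenerate curve: lambda has no spread.", call. = FALSE)
  }

  # secant slope over the first 2% strain as the small-strain estimate of E
  small <- which(lambda <= 1.02 & lambda > 1)
  E0 <- if (length(small) >= 2L) {
    s <- stats::coef(stats::lm(sigma[small] ~ I(lambda[small] - 1)))[2L]
    max(as.numeric(s), 1e-3)
  } else {
    max((sigma[length(sigma)] - sigma[1L]) / (lambda[length(lambda)] - lambda[1L]), 1e-3)
  }

  dat <- data.frame(lambda = lambda, sigma = sigma)
  fit <- try(minpack.lm::nlsLM(
    sigma ~ vw_stress(lambda, E, gamma),
    data = dat,
    start = list(E = E0, gamma = 1),
    lower = c(E = .Machine$double.eps, gamma = 0),
    upper = c(E = Inf, gamma = gamma_max),
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    silent = TRUE)

  if (inherits(fit, "try-error") || !fit$convInfo$isConv) {
    return(structure(list(E_pa = NA_real_, gamma = NA_real_,
                          se = c(E = NA_real_, gamma = NA_real_),
                          rss = NA_real_, r_squared = NA_real_,
                          n_points = length(lambda), converged = FALSE),
                     class = "vw_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(E = NA_real_, gamma = NA_real_))
  res <- stats::resid(fit)
  rss <- sum(res^2)
  tss <- sum((sigma - mean(sigma))^2)
  structure(
    list(E_pa = unname(est["E"]), gamma = unname(est["gamma"]),
         se = c(E = unname(se[1L]), gamma = unname(se[2L])),
         rss = rss, r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         n_points = length(lambda), converged = TRUE),
    class = "vw_fit")
}

#' @export
print.vw_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Veronda-Westman fit: did not converge (n =", x$n_points, ")\n")
    return(invisible(x))
  }
  cat(sprintf("Veronda-Westman fit (n = %d)\n", x$n_points))
  cat(sprintf("  E     = %.4g Pa  (SE %.3g)\n", x$E_pa, x$se[["E"]]))
  cat(sprintf("  gamma = %.4g     (SE %.3g)\n", x$gamma, x$se[["gamma"]]))
  cat(sprintf("  R^2   = %.6f, RSS = %.4g\n", x$r_squared, x$rss))
  invisible(x)
}
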