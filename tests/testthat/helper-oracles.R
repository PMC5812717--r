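# Independent oracles used to cross-check the package implementations.
# Each is a deliberately naive, brute-force or closed-form computation that
# shares no code with the functions it checks.

# Direct scalar evaluation of the Veronda-Westman uniaxial stress.
oracle_vw_scalar <- function(lambda, E, gamma) {
  (2 * E / 3) * (lambda^2 - 1 / lambda) *
    (exp(gamma * (lambda^2 + 2 / lambda - 3)) - 1 / (2 * lambda))
}

# Central finite-difference slope of a function at a point.
oracle_num_slope <- function(f, x, h = 1e-6) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Brute-force dense-lag cross-correlation delay: cubic-spline upsample both
# traces onto a fine grid and scan every fine lag for the maximum of the
# normalized correlation.
oracle_dense_delay <- function(ref, trace, frame_interval_s, upsample = 100L) {
  n <- length(ref)
  t0 <- seq_len(n)
  tf <- seq(1, n, by = 1 / upsample)
  a <- stats::spline(t0, ref, xout = tf)$y
  b <- stats::spline(t0, trace, xout = tf)$y
  m <- length(a)
  max_lag <- m - 1L
  lags <- seq.int(-max_lag, max_lag)
  best <- -Inf; best_lag <- 0L
  denom <- sqrt(sum(a^2) * sum(b^2))
  for (l in lags) {
    i <- seq_len(m)
    j <- i + l
    ok <- j >= 1L & j <= m
    v <- sum(a[i[ok]] * b[j[ok]]) / denom
    if (v > best) { best <- v; best_lag <- l }
  }
  (best_lag / upsample) * frame_interval_s
}

# Normal-equations OLS: beta = (X'X)^-1 X'y with an explicit intercept.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1L]
}

oracle_r2 <- function(X, y) {
  beta <- oracle_ols(X, y)
  res <- y - cbind(1, as.matrix(X)) %*% beta
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Two-line mean/SD exclusion oracle for breath-frequency filtering.
oracle_filter <- function(f) {
  which(abs(f - mean(f)) > stats::sd(f))
}
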