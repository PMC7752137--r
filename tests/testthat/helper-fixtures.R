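# shared fixtures and independent oracles built in code at test time

acq_tr <- c(50, 150, 275, 450, 600)
acq_te <- c(12.2, 36.6, 60.94)

# regular polygon approximating a circle (or similar ellipse)
circle_poly <- function(r = 1, n = 64, center = c(0, 0), aspect = 1,
                        phase = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * sqrt(aspect) * cos(th + phase),
        center[2] + r * sin(th + phase) / sqrt(aspect))
}

# adaptive-quadrature arc-length oracle for an axis-aligned ellipse with
# semi-axes a, b
ellipse_perimeter_oracle <- function(a, b) {
  4 * integrate(function(th) sqrt((a * sin(th))^2 + (b * cos(th))^2),
                0, pi / 2, rel.tol = 1e-12)$value
}

# exhaustive two-sided permutation test on the difference of means
permutation_p_two_sided <- function(a, b) {
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  obs <- abs(mean(a) - mean(b))
  stats <- apply(idx, 2, function(i)
    abs(mean(pool[i]) - mean(pool[-i])))
  mean(stats >= obs - 1e-12)
}

# numerical-integration oracle for the mean of a Rician(nu, sigma) variate
rician_mean_oracle <- function(nu, sigma) {
  # density rewritten with the exponentially scaled Bessel I0 so the
  # integrand stays finite at high SNR
  integrate(function(x)
    x * (x / sigma^2) * exp(-(x - nu)^2 / (2 * sigma^2)) *
      besselI(x * nu / sigma^2, 0, expon.scaled = TRUE),
    0, nu + 12 * sigma, rel.tol = 1e-10)$value
}

# numerically integrated Student-t CDF (independent of stats::pt)
t_cdf_oracle <- function(q, df) {
  dens <- function(x) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  if (q >= 0) 0.5 + integrate(dens, 0, q, rel.tol = 1e-12)$value
  else 0.5 - integrate(dens, q, 0, rel.tol = 1e-12)$value
}

# tiny phantom used across module tests
tiny_phantom <- function(...) make_phantom(phantom_spec(grid = c(24, 12, 14),
                                                        voxel_size_mm = 0.2,
                                                        ...))

# tiny noiseless T2 series (fast to fit)
tiny_t2_series <- function(ph = tiny_phantom(), ...)
  simulate_series(ph, "T2", ...)
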