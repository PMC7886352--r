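# Independent numerical oracles, deliberately distinct from the package's
# closed forms: adaptive quadrature of the label convolution integral, and
# a fixed-step RK4 integrator for the full source/division ODE systems.

# l(t) = p c int_0^t U(s) e^{-p(t-s)} ds by adaptive quadrature, split at
# tau where U has a kink.
oracle_label_fraction <- function(t, p, bw, c_amp = 1) {
  u <- function(s) body_water(s, bw)
  vapply(t, function(tt) {
    if (tt == 0 || p == 0) return(0)
    integrand <- function(s) u(s) * exp(-p * (tt - s))
    cuts <- sort(unique(c(0, min(bw$tau, tt), tt)))
    total <- 0
    for (i in seq_len(length(cuts) - 1)) {
      if (cuts[i + 1] <= cuts[i]) next
      total <- total + stats::integrate(integrand, cuts[i], cuts[i + 1],
                                        rel.tol = 1e-12,
                                        abs.tol = 1e-14)$value
    }
    p * c_amp * total
  }, numeric(1))
}

# Classic RK4 over a fixed grid; deriv(t, y) returns dy/dt. Returns the
# state matrix at the requested observation times (which must lie on the
# step grid up to rounding).
oracle_rk4 <- function(deriv, y0, t_obs, h = 0.01) {
  ts <- sort(unique(c(0, t_obs)))
  y <- y0
  out <- matrix(NA_real_, length(ts), length(y0))
  out[1, ] <- y0
  for (i in seq_len(length(ts) - 1)) {
    t0 <- ts[i]; t1 <- ts[i + 1]
    nstep <- max(1L, ceiling((t1 - t0) / h))
    dt <- (t1 - t0) / nstep
    tt <- t0
    for (s in seq_len(nstep)) {
      k1 <- deriv(tt, y)
      k2 <- deriv(tt + dt / 2, y + dt / 2 * k1)
      k3 <- deriv(tt + dt / 2, y + dt / 2 * k2)
      k4 <- deriv(tt + dt, y + dt * k3)
      y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      tt <- tt + dt
    }
    out[i + 1, ] <- y
  }
  out[match(t_obs, ts), , drop = FALSE]
}

# Labeled fraction from the explicit source/division system
#   dN/dt = sigma + p_div N - d N
#   dL/dt = sigma c U + p_div c U N - d L
# (naive-compartment bookkeeping with total labeled DNA L).
oracle_source_system <- function(t_obs, sigma, p_div, d, N0, bw, c_amp,
                                 h = 0.01) {
  deriv <- function(tt, y) {
    u <- body_water(tt, bw)
    c(sigma + (p_div - d) * y[1],
      sigma * c_amp * u + p_div * c_amp * u * y[1] - d * y[2])
  }
  st <- oracle_rk4(deriv, c(N0, 0), t_obs, h)
  st[, 2] / st[, 1]
}

# Labeled fraction from the peripheral-subset system
#   dX/dt = p X - d X,  dL/dt = p c U X - d L.
oracle_division_system <- function(t_obs, p, d, X0, bw, c_amp, h = 0.01) {
  deriv <- function(tt, y) {
    u <- body_water(tt, bw)
    c((p - d) * y[1],
      p * c_amp * u * y[1] - d * y[2])
  }
  st <- oracle_rk4(deriv, c(X0, 0), t_obs, h)
  st[, 2] / st[, 1]
}

# Exact two-sided Mann-Whitney p-value by independent enumeration (rank-sum
# deviation from its mean), used as the oracle for compare_groups.
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  splits <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(r[splits], nrow = nx))
  mu <- nx * (nx + ny + 1) / 2
  w_obs <- sum(r[seq_len(nx)])
  min(1, mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
}
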