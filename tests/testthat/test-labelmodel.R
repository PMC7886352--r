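test_that("body-water curve honors initial condition, plateau and continuity", {
  bw <- fix_bw()
  expect_equal(body_water(0, bw), bw$beta)
  # asymptote with label never withdrawn
  bw_inf <- body_water_params(0.015, 0.07, 0.007, Inf)
  expect_equal(body_water(1e5, bw_inf), bw_inf$f, tolerance = 1e-10)
  # continuity at tau
  expect_lt(abs(body_water(42, bw) - body_water(42 + 1e-9, bw)), 1e-10)
  # vectorized, monotone washout after tau
  t <- c(50, 100, 200)
  expect_true(all(diff(body_water(t, bw)) < 0))
  expect_error(body_water(-1, bw), "t must be")
  expect_error(body_water_params(0.015, -0.1, 0.007, 42), "delta")
  expect_error(body_water_params(1.5, 0.07, 0.007, 42), "f must be")
})

test_that("mono label fraction matches closed-form and quadrature oracles", {
  # constant U == f during labeling: l(t) = c f (1 - e^{-pt})
  bw_flat <- body_water_params(0.02, 0.07, 0.02, 42)
  expect_equal(mono_label_fraction(10, 0.1, bw_flat, 1),
               0.02 * (1 - exp(-1)), tolerance = 1e-12)
  bw <- fix_bw()
  expect_equal(mono_label_fraction(c(5, 50, 300), 0, bw, 4), c(0, 0, 0))
  expect_equal(mono_label_fraction(0, 0.3, bw, 4), 0)
  # p = delta degenerate case handled by the analytic limit, and a p just
  # off the singularity must agree with adaptive quadrature
  t <- c(1, 7, 21, 42, 63, 120, 365)
  for (p in c(bw$delta, bw$delta + 1e-9, 0.01, 0.5)) {
    expect_lt(max(abs(mono_label_fraction(t, p, bw, 3) -
                        oracle_label_fraction(t, p, bw, 3))), 1e-8)
  }
  expect_error(mono_label_fraction(5, -0.1, bw), "p must be")
})

test_that("mixtures collapse, stay convex and plateau at c f", {
  bw <- fix_bw()
  t <- c(7, 21, 42, 120, 364)
  m1 <- kinetic_mixture(1, 0.05, 4)
  expect_equal(mixture_label_fraction(t, m1, bw),
               mono_label_fraction(t, 0.05, bw, 4))
  m_same <- kinetic_mixture(c(0.5, 0.5), c(0.05, 0.05), 4)
  expect_equal(mixture_label_fraction(t, m_same, bw),
               mono_label_fraction(t, 0.05, bw, 4))
  m <- kinetic_mixture(c(0.9, 0.1), c(0.001, 0.1), 4)
  lo <- pmin(mono_label_fraction(t, 0.001, bw, 4),
             mono_label_fraction(t, 0.1, bw, 4))
  hi <- pmax(mono_label_fraction(t, 0.001, bw, 4),
             mono_label_fraction(t, 0.1, bw, 4))
  v <- mixture_label_fraction(t, m, bw)
  expect_true(all(v >= lo - 1e-15 & v <= hi + 1e-15))
  # label saturates at c f when administration never ends
  bw_inf <- body_water_params(0.015, 0.07, 0.007, Inf)
  m2 <- kinetic_mixture(c(0.3, 0.7), c(0.2, 0.01), 4)
  expect_equal(mixture_label_fraction(5000, m2, bw_inf), 4 * 0.015,
               tolerance = 1e-6)
  # bounded by c max U and nondecreasing during labeling when beta <= f
  tt <- seq(0, 42, by = 1)
  v2 <- mixture_label_fraction(tt, m2, bw)
  expect_true(all(diff(v2) >= 0))
  expect_true(all(v2 <= 4 * max(body_water(tt, bw)) + 1e-12))
})

test_that("kinetic mixtures validate and order components by rate", {
  m <- kinetic_mixture(c(0.9, 0.1), c(0.001, 0.1), 2)
  expect_equal(m$rates, c(0.1, 0.001))
  expect_equal(m$alphas, c(0.1, 0.9))
  expect_equal(average_production_rate(m), 0.0109)
  expect_equal(average_production_rate(kinetic_mixture(1, 0.05)), 0.05)
  expect_equal(average_production_rate(
    kinetic_mixture(c(0.5, 0.5), c(0, 0))), 0)
  expect_error(kinetic_mixture(c(0.5, 0.4), c(0.1, 0.01)), "sum to 1")
  expect_error(kinetic_mixture(rep(1 / 3, 3), c(0.1, 0.01, 0.001)),
               "1 or 2")
  expect_error(kinetic_mixture(1, -0.1), "rates")
})

test_that("enrichment series enforce their invariants", {
  expect_error(enrichment_series("a", "plasma", 1:3, rep(0.1, 3)),
               "unknown compartment")
  expect_error(enrichment_series("a", "urine", c(1, 1, 2), rep(0.1, 3)),
               "strictly increasing")
  expect_error(enrichment_series("a", "urine", 1:3, c(0.1, -0.1, 0.2)),
               ">= 0")
  expect_error(enrichment_series("a", "naive_cd4", 1:3, c(0.1, 2, 0.2),
                                 scaled = TRUE), "sanity bound")
})

test_that("granulocyte scaling divides by the fitted maximum", {
  s <- enrichment_series("a", "naive_cd4", c(7, 14), c(0.009, 0.018))
  out <- granulocyte_scale(0.018, s)
  expect_equal(out$values, c(0.5, 1.0))
  expect_true(out$scaled)
  expect_equal(attr(out, "scale_M"), 0.018)
  zero <- enrichment_series("a", "naive_cd4", c(7, 14), c(0, 0))
  expect_equal(granulocyte_scale(0.018, zero)$values, c(0, 0))
  expect_error(granulocyte_scale(0.018, out), "already scaled")
  expect_error(granulocyte_scale(-1, s), "maximum <= 0")
})

test_that("isotope calibration inverts the log-log standard line", {
  known <- lk_isotope_standards
  # perfect standards: correction is the identity
  std <- data.frame(known_ttr = known, measured_ttr = known)
  expect_equal(calibrate_isotope_ratio(std, c(0.005, 0.05)),
               c(0.005, 0.05), tolerance = 1e-10, ignore_attr = TRUE)
  # proportional response measured = k * known: 2-point log-linear system
  # solved by hand gives corrected = measured / k
  k <- 1.3
  std2 <- data.frame(known_ttr = c(0, 0.0016, 0.0032),
                     measured_ttr = c(0, 0.0016, 0.0032) * k)
  expect_equal(calibrate_isotope_ratio(std2, 0.0026), 0.0026 / k,
               tolerance = 1e-10, ignore_attr = TRUE)
  # sample at the zero standard returns 0 with a flag
  std3 <- data.frame(known_ttr = known,
                     measured_ttr = known + 0.001)
  expect_warning(out <- calibrate_isotope_ratio(std3, 0.001), "baseline")
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "below_baseline"))
  # monotone in the input
  vals <- calibrate_isotope_ratio(std3, c(0.002, 0.01, 0.05))
  expect_true(all(diff(vals) > 0))
})
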