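test_that("noise-free body-water + granulocyte data are recovered to 1e-4", {
  dat <- fix_bodywater_data()
  fit <- fit_body_water_and_granulocytes(dat$urine, dat$gran, tau = 42,
                                         seed = 1)
  truth <- c(f = 0.015, delta = 0.07, beta = 0.007, p_gran = 0.3, c_amp = 4)
  expect_lt(max(abs(fit$estimates[names(truth)] - truth) / truth), 1e-4)
  expect_equal(fit$params$M, fix_M(), tolerance = 1e-4)
  expect_true(is.finite(fit$loglik))
  expect_equal(length(fit$residuals$urine), length(dat$urine$times))
})

test_that("body-water fit enforces its preconditions", {
  dat <- fix_bodywater_data()
  empty <- enrichment_series("T1", "granulocytes", numeric(0), numeric(0))
  expect_error(fit_body_water_and_granulocytes(dat$urine, empty), ">= 4")
  expect_error(fit_body_water_and_granulocytes(dat$gran, dat$gran),
               "compartment 'urine'")
})

test_that("f is recovered within 10% at transformed-scale noise 0.01", {
  # Verified by simulation: at this noise and the default 11-point urine
  # schedule the ML estimate of f carries ~7% median relative error (the
  # fits beat the truth in likelihood, so this is the information limit of
  # the design, not an optimizer artifact); 10% guards against regressions.
  errs <- vapply(1:10, function(s) {
    dat <- fix_bodywater_data(sd = 0.01, seed = s)
    fit <- fit_body_water_and_granulocytes(dat$urine, dat$gran, tau = 42,
                                           seed = 1)
    abs(fit$estimates["f"] - 0.015) / 0.015
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("noise-free 1-component subset data are recovered to 1e-3", {
  bw <- fix_bw(); M <- fix_M()
  dat <- fix_subset_data(kinetic_mixture(1, 0.02, 4), d = 0.03, X0 = 2e5,
                         compartment = "naive_cd4")
  fit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 1, seed = 7)
  expect_lt(abs(fit$estimates["p"] - 0.02) / 0.02, 1e-3)
  expect_lt(abs(fit$estimates["d"] - 0.03) / 0.03, 1e-3)
  expect_lt(abs(fit$estimates["X0"] - 2e5) / 2e5, 1e-3)
})

test_that("noise-free 2-component subset data are recovered", {
  bw <- fix_bw(); M <- fix_M()
  mix <- kinetic_mixture(c(0.8, 0.2), c(0.005, 0.2), 4)
  dat <- fix_subset_data(mix, d = average_production_rate(mix), X0 = 2e5)
  fit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 2, seed = 7)
  expect_equal(unname(fit$estimates["p"]), average_production_rate(mix),
               tolerance = 1e-3)
  expect_equal(unname(fit$estimates[c("p1", "p2")]), c(0.2, 0.005),
               tolerance = 1e-2)
  expect_equal(unname(fit$estimates["alpha1"]), 0.2, tolerance = 1e-2)
})

test_that("constant counts force the steady-state limit d = p", {
  bw <- fix_bw(); M <- fix_M()
  dat <- fix_subset_data(kinetic_mixture(1, 0.015, 4), d = 0.015, X0 = 2e5,
                         compartment = "naive_cd4")
  fit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 1, seed = 7)
  expect_equal(unname(fit$estimates["d"]), unname(fit$estimates["p"]),
               tolerance = 1e-6)
})

test_that("subset fit enforces identifiability preconditions", {
  bw <- fix_bw(); M <- fix_M()
  dat <- fix_subset_data(kinetic_mixture(1, 0.02, 4), d = 0.02, X0 = 2e5)
  short <- enrichment_series("T1", "naive_cd4", dat$enr$times[1:7],
                             dat$enr$values[1:7], scaled = TRUE)
  expect_error(fit_subset(short, dat$counts, bw, 4, M, 2), "under-identified")
  tiny <- enrichment_series("T1", "naive_cd4", dat$enr$times[1:5],
                            dat$enr$values[1:5], scaled = TRUE)
  expect_error(fit_subset(tiny, dat$counts, bw, 4, M, 1), ">= 6")
  expect_error(fit_subset(dat$enr, dat$counts[1:3, ], bw, 4, M, 1), ">= 4")
  unscaled <- enrichment_series("T1", "naive_cd4", dat$enr$times,
                                dat$enr$values, scaled = FALSE)
  expect_error(fit_subset(unscaled, dat$counts, bw, 4, M, 1), "scaled")
})

test_that("component selection follows the extra-sum-of-squares F-test", {
  bw <- fix_bw(); M <- fix_M()
  mix <- kinetic_mixture(c(0.7, 0.3), c(0.005, 0.3), 4)
  dat <- fix_subset_data(mix, d = average_production_rate(mix), X0 = 2e5,
                         sd_enr = 0.02, sd_cnt = 0.05, seed = 3)
  fit1 <- fit_subset(dat$enr, dat$counts, bw, 4, M, 1, seed = 1)
  fit2 <- fit_subset(dat$enr, dat$counts, bw, 4, M, 2, seed = 1)
  sel <- select_components(fit1, fit2)
  expect_equal(as.integer(sel), 2L)
  expect_lt(attr(sel, "p_value"), 0.05)
  # identical enrichment RSS: no improvement, keep the simpler model
  fit2_same <- fit2
  fit2_same$rss$enrichment <- fit1$rss$enrichment
  expect_equal(as.integer(select_components(fit1, fit2_same)), 1L)
  # worse 2-component fit trips the optimizer-failure guard
  fit2_bad <- fit2
  fit2_bad$rss$enrichment <- fit1$rss$enrichment * 1.5
  expect_warning(sel_bad <- select_components(fit1, fit2_bad), "worse")
  expect_equal(as.integer(sel_bad), 1L)
  # different data are refused
  other <- fix_subset_data(mix, d = average_production_rate(mix), X0 = 2e5,
                           sd_enr = 0.02, seed = 99)
  fit_other <- fit_subset(other$enr, other$counts, bw, 4, M, 1, seed = 1)
  expect_error(select_components(fit_other, fit2), "identical data")
})

test_that("bootstrap CIs are deterministic, degenerate on noise-free data, and bracket the estimate", {
  bw <- fix_bw(); M <- fix_M()
  dat <- fix_subset_data(kinetic_mixture(1, 0.02, 4), d = 0.03, X0 = 2e5,
                         compartment = "naive_cd4")
  fit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 1, seed = 7)
  b1 <- bootstrap_ci(fit, n_boot = 120, seed = 5)
  b2 <- bootstrap_ci(fit, n_boot = 120, seed = 5)
  expect_identical(b1$ci95, b2$ci95)
  expect_lt(max(b1$ci95["p", 2] - b1$ci95["p", 1],
                b1$ci95["d", 2] - b1$ci95["d", 1]), 1e-3)
  expect_error(bootstrap_ci(fit, n_boot = 50), ">= 100")
  # noisy data: percentile interval brackets the point estimate
  noisy <- fix_subset_data(kinetic_mixture(1, 0.02, 4), d = 0.03, X0 = 2e5,
                           sd_enr = 0.02, sd_cnt = 0.05, seed = 2,
                           compartment = "naive_cd4")
  nf <- fit_subset(noisy$enr, noisy$counts, bw, 4, M, 1, seed = 7)
  nb <- bootstrap_ci(nf, n_boot = 120, seed = 5)
  est <- nf$estimates[rownames(nb$ci95)]
  expect_true(all(nb$ci95[, 1] <= est + 1e-12 & est <= nb$ci95[, 2] + 1e-12))
  # bodywater fits bootstrap too
  bwd <- fix_bodywater_data(sd = 0.01, seed = 4)
  bwf <- fit_body_water_and_granulocytes(bwd$urine, bwd$gran, 42, seed = 1)
  bwb <- bootstrap_ci(bwf, n_boot = 100, seed = 9)
  expect_true(all(bwb$ci95[, 1] <= bwb$ci95[, 2]))
})

test_that("selected fit beats every multi-start candidate", {
  bw <- fix_bw(); M <- fix_M()
  dat <- fix_subset_data(kinetic_mixture(c(0.8, 0.2), c(0.005, 0.2), 4),
                         d = 0.044, X0 = 2e5, sd_enr = 0.02, sd_cnt = 0.05,
                         seed = 6)
  fit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 2, seed = 1)
  expect_lte(fit$objective_value,
             min(fit$multistart_values, na.rm = TRUE) + 1e-9)
  # stability: a different multi-start seed lands on the same optimum
  refit <- fit_subset(dat$enr, dat$counts, bw, 4, M, 2, seed = 2)
  expect_lt(abs(fit$loglik - refit$loglik) / abs(fit$loglik), 0.05)
})
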