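# Shared fixture builders: a canonical body-water curve, the default
# schedule, and noise-free / noisy subset datasets generated in code.

fix_bw <- function(tau = 42) body_water_params(0.015, 0.07, 0.007, tau)

fix_sched <- function(tau = 42) lk_default_schedule(tau)

# True granulocyte scaling maximum for fix_bw() with p_gran = 0.3, c = 4.
fix_M <- function(bw = fix_bw(), p_gran = 0.3, c_amp = 4) {
  sch <- fix_sched(bw$tau)
  grid <- seq(min(sch$blood_days), max(sch$blood_days), length.out = 1000)
  max(mono_label_fraction(grid, p_gran, bw, c_amp))
}

# Scaled enrichment series + count table for one subset, with optional
# Gaussian noise on the fitter's transformed scales.
fix_subset_data <- function(mix, d, X0, bw = fix_bw(), M = fix_M(bw),
                            sd_enr = 0, sd_cnt = 0, seed = 1,
                            compartment = "memory_cd4") {
  sch <- fix_sched(bw$tau)
  p <- average_production_rate(mix)
  model <- pmin(mixture_label_fraction(sch$blood_days, mix, bw) / M, 1)
  cnt_model <- X0 * exp((p - d) * sch$blood_days)
  withr::with_seed(seed, {
    vals <- if (sd_enr > 0) {
      sin(asin(sqrt(model)) + stats::rnorm(length(model), 0, sd_enr))^2
    } else model
    cnts <- if (sd_cnt > 0) {
      10^(log10(cnt_model) + stats::rnorm(length(cnt_model), 0, sd_cnt))
    } else cnt_model
    list(enr = enrichment_series("T1", compartment, sch$blood_days, vals,
                                 scaled = TRUE),
         counts = data.frame(time_days = sch$blood_days, count = cnts))
  })
}

# Noise-free urine + granulocyte series for the body-water fit.
fix_bodywater_data <- function(bw = fix_bw(), p_gran = 0.3, c_amp = 4,
                               sd = 0, seed = 1) {
  sch <- fix_sched(bw$tau)
  u_model <- body_water(sch$urine_days, bw)
  g_model <- mono_label_fraction(sch$blood_days, p_gran, bw, c_amp)
  withr::with_seed(seed, {
    noisy <- function(m) {
      if (sd == 0) return(m)
      sin(asin(sqrt(pmin(m, 1))) + stats::rnorm(length(m), 0, sd))^2
    }
    list(urine = enrichment_series("T1", "urine", sch$urine_days, noisy(u_model)),
         gran = enrichment_series("T1", "granulocytes", sch$blood_days,
                                  noisy(g_model)))
  })
}
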