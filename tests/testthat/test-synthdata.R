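test_that("generation is deterministic and exact at zero noise", {
  cfg <- paper_like_config("patient", subsets = c("naive_cd4", "memory_cd4"))
  a <- generate_individual(cfg, seed = 42)
  b <- generate_individual(cfg, seed = 42)
  expect_identical(a$enrichment, b$enrichment)
  expect_identical(a$counts, b$counts)
  expect_identical(a$qpcr, b$qpcr)
  d <- generate_individual(cfg, seed = 43)
  expect_false(identical(a$enrichment$enrichment, d$enrichment$enrichment))

  cfg0 <- cfg
  cfg0$noise <- list(sd_enrichment = 0, sd_counts = 0, sd_ct = 0)
  z <- generate_individual(cfg0, seed = 1)
  bw <- cfg0$bw
  urine <- z$enrichment[z$enrichment$compartment == "urine", ]
  expect_equal(urine$enrichment, body_water(urine$time_days, bw))
  gran <- z$enrichment[z$enrichment$compartment == "granulocytes", ]
  expect_equal(gran$enrichment,
               mono_label_fraction(gran$time_days, cfg0$gran$p, bw,
                                   cfg0$gran$c))
  nc4 <- z$enrichment[z$enrichment$compartment == "naive_cd4", ]
  s <- cfg0$subsets$naive_cd4
  expect_equal(nc4$enrichment,
               mixture_label_fraction(nc4$time_days,
                                      kinetic_mixture(s$alphas, s$rates,
                                                      cfg0$gran$c), bw),
               tolerance = 1e-12)
  cc <- z$counts[z$counts$subset == "naive_cd4", ]
  expect_equal(cc$subset_count_per_ml,
               s$X0 * exp((sum(s$alphas * s$rates) - s$d) * cc$time_days))
})

test_that("explicit-source mode matches the per-cell-rate closed form when N is constant", {
  cfg <- paper_like_config("patient", subsets = "naive_cd4")
  p_div <- 0.001; d <- 0.004; N0 <- 1e5
  sigma <- (d - p_div) * N0  # keeps N exactly constant
  cfg$subsets$naive_cd4 <- list(sigma = sigma, p_div = p_div, d = d, N0 = N0)
  cfg$noise <- list(sd_enrichment = 0, sd_counts = 0, sd_ct = 0)
  z <- generate_individual(cfg, seed = 1)
  got <- z$enrichment[z$enrichment$compartment == "naive_cd4", "enrichment"]
  p_eff <- sigma / N0 + p_div
  want <- mono_label_fraction(fix_sched()$blood_days, p_eff, cfg$bw,
                              cfg$gran$c)
  expect_lt(max(abs(got - want)), 1e-6)
  cc <- z$counts[z$counts$subset == "naive_cd4", ]
  expect_equal(cc$subset_count_per_ml, rep(N0, nrow(cc)), tolerance = 1e-9)
})

test_that("generated subset curves respect the granulocyte plateau ordering", {
  for (grp in c("patient", "healthy_control")) {
    cfg <- paper_like_config(grp)
    cfg$noise <- list(sd_enrichment = 0, sd_counts = 0, sd_ct = 0)
    z <- generate_individual(cfg, seed = 1)
    gran_max <- max(z$enrichment$enrichment[
      z$enrichment$compartment == "granulocytes"])
    plateau <- cfg$gran$c * cfg$bw$f
    expect_lt(abs(gran_max - plateau) / plateau, 0.15)
    for (nm in lk_subsets) {
      vals <- z$enrichment$enrichment[z$enrichment$compartment == nm]
      expect_true(all(vals <= plateau * 1.0001))
    }
  }
})

test_that("qPCR tables invert to the configured division history", {
  cfg <- paper_like_config("patient", subsets = "naive_b")
  cfg$noise <- list(sd_enrichment = 0, sd_counts = 0, sd_ct = 0)
  z <- generate_individual(cfg, seed = 1)
  q <- z$qpcr
  get_ct <- function(flag, target) {
    q$ct_mean[q$control_flag == flag & q$target == target]
  }
  sample <- qpcr_measurement(get_ct(FALSE, "signal"), get_ct(FALSE, "coding"),
                             get_ct(FALSE, "albumin"))
  control <- qpcr_measurement(get_ct(TRUE, "signal"), get_ct(TRUE, "coding"),
                              get_ct(TRUE, "albumin"), is_control_line = TRUE)
  expect_equal(as.numeric(replication_history(sample, control)),
               cfg$qpcr$divisions, tolerance = 1e-9)
  expect_equal(as.numeric(coding_joint_fraction(sample, control)),
               cfg$qpcr$coding_fraction, tolerance = 1e-9)
  expect_equal(as.numeric(trec_content(z$trec$trec_copies[1],
                                       z$trec$cell_equivalents[1])),
               unname(cfg$qpcr$trec_per_cell["naive_cd4"]), tolerance = 1e-2)
})

test_that("cohorts carry group structure, taus and a truth table", {
  co <- generate_cohort(2, 3, seed = 7,
                        patient_cfg = paper_like_config("patient",
                                                        subsets = "naive_cd4"),
                        control_cfg = paper_like_config("healthy_control",
                                                        subsets = "naive_cd4"))
  expect_equal(sum(co$individuals$group == "patient"), 2)
  expect_equal(sum(co$individuals$group == "healthy_control"), 3)
  expect_equal(unique(co$individuals$tau[co$individuals$group == "patient"]), 42)
  expect_equal(unique(co$individuals$tau[co$individuals$group ==
                                           "healthy_control"]), 63)
  expect_equal(nrow(co$truth_table), 5)
  expect_true(all(co$truth_table$p_true > 0))
  # controls stay near steady state: |r| small relative to p
  con <- co$truth_table[co$truth_table$group == "healthy_control", ]
  expect_true(all(abs(con$p_true - con$d_true) <= 0.75 * con$p_true))
  co2 <- generate_cohort(2, 3, seed = 7,
                         patient_cfg = paper_like_config("patient",
                                                         subsets = "naive_cd4"),
                         control_cfg = paper_like_config("healthy_control",
                                                         subsets = "naive_cd4"))
  expect_identical(co$enrichment, co2$enrichment)
})

test_that("truth configs round-trip through YAML serialization", {
  cfg <- paper_like_config("patient", subsets = c("naive_cd4", "naive_b"))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), path)
  back <- yaml::read_yaml(path)
  expect_equal(back$bw$f, cfg$bw$f)
  expect_equal(back$subsets$naive_b$rates, cfg$subsets$naive_b$rates)
  expect_equal(back$schedule$blood_days, cfg$schedule$blood_days)
})

test_that("schedules missing a labeling or de-labeling phase are rejected", {
  cfg <- paper_like_config("patient", subsets = "naive_cd4")
  bad <- cfg$schedule
  bad$blood_days <- c(7, 63, 91, 126)  # single labeling-phase draw
  expect_error(truth_config(cfg$individual, cfg$group, cfg$bw, cfg$gran,
                            cfg$subsets, cfg$leukocyte, schedule = bad),
               "labeling phase")
  bad2 <- cfg$schedule
  bad2$blood_days <- c(7, 14, 28, 42)
  expect_error(truth_config(cfg$individual, cfg$group, cfg$bw, cfg$gran,
                            cfg$subsets, cfg$leukocyte, schedule = bad2),
               "de-labeling")
})
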