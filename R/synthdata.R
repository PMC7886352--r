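# Synthetic labeling-study generator: complete heavy-water studies with
# known ground truth, defaulting to the study design being modeled
# (six-week labeling in patients, nine weeks in controls, 4 + 6 blood
# draws over ~1 year, urine in the first 13 weeks).

#' Default sampling schedule
#'
#' Four blood draws during the labeling period and six during de-labeling,
#' the last about one year after the first label intake; urine sampled
#' through the first 13 weeks.
#'
#' @param tau End of label administration (days): 42 (patients) or 63
#'   (controls).
#' @return List with `blood_days` and `urine_days`.
#' @export
lk_default_schedule <- function(tau = 42) {
  blood <- if (tau <= 42) {
    c(7, 14, 28, 42, 63, 91, 126, 182, 273, 364)
  } else {
    c(10, 21, 42, 63, 84, 112, 147, 203, 287, 364)
  }
  urine <- sort(unique(pmin(c(1, 3, 7, 14, 21, 28, 35, tau, tau + 14, 77, 91),
                            91)))
  list(blood_days = blood, urine_days = urine)
}

#' Ground-truth configuration for one synthetic individual
#'
#' Bundles every generating parameter: body-water curve, granulocyte
#' kinetics, per-subset kinetic mixtures with loss rates and inclusion
#' counts, leukocyte trend, noise levels and the sampling schedule. Noise is
#' injected on the same transformed scales the fitter assumes: Gaussian on
#' the arcsin-sqrt scale for enrichment (sd 0.02 by default) and on the
#' log10 scale for counts (sd 0.05), so parameter-recovery tests probe the
#' estimator rather than noise-model mismatch. A misspecified-noise mode
#' (`noise_scale = "raw"`, additive on the raw enrichment scale) exists for
#' robustness checks.
#'
#' @param individual Identifier.
#' @param group `"patient"` or `"healthy_control"`.
#' @param bw [body_water_params].
#' @param gran List `p` (per day) and `c` (amplification factor).
#' @param subsets Named list; each element a list with `alphas`, `rates`,
#'   `d`, `X0` and optionally `sigma`, `p_div`, `N0` for the explicit-source
#'   mode (see [generate_individual]).
#' @param leukocyte List `intercept` (cells/ml) and `slope` (cells/ml/day).
#' @param noise List `sd_enrichment`, `sd_counts`, `sd_ct`.
#' @param schedule List `blood_days`, `urine_days`; defaults to
#'   [lk_default_schedule] at `bw$tau`.
#' @param qpcr List `divisions`, `coding_fraction` (percent),
#'   `trec_per_cell` (named by subset).
#' @param noise_scale `"transformed"` (default) or `"raw"`.
#' @return Object of class `truth_config`.
#' @export
truth_config <- function(individual, group, bw, gran, subsets, leukocyte,
                         noise = list(sd_enrichment = 0.02, sd_counts = 0.05,
                                      sd_ct = 0.15),
                         schedule = lk_default_schedule(bw$tau),
                         qpcr = NULL,
                         noise_scale = c("transformed", "raw")) {
  stopifnot(inherits(bw, "body_water_params"),
            is.list(gran), all(c("p", "c") %in% names(gran)),
            is.list(subsets), length(subsets) >= 1,
            !is.null(names(subsets)), all(names(subsets) %in% lk_subsets),
            is.list(leukocyte),
            all(c("intercept", "slope") %in% names(leukocyte)))
  noise_scale <- match.arg(noise_scale)
  n_label <- sum(schedule$blood_days <= bw$tau)
  if (n_label < 2) stop("schedule must place >= 2 blood draws in the labeling phase")
  if (!any(schedule$blood_days > bw$tau)) {
    stop("schedule must cover the de-labeling phase")
  }
  for (nm in names(subsets)) {
    s <- subsets[[nm]]
    if (is.null(s$sigma)) {
      stopifnot(all(c("alphas", "rates", "d", "X0") %in% names(s)))
      kinetic_mixture(s$alphas, s$rates, gran$c)  # validates
    } else {
      stopifnot(all(c("sigma", "p_div", "d", "N0") %in% names(s)))
    }
    if (s$d < 0) stop("loss rate d must be >= 0 for subset ", nm)
  }
  structure(list(individual = as.character(individual), group = group,
                 bw = bw, gran = gran, subsets = subsets,
                 leukocyte = leukocyte, noise = noise, schedule = schedule,
                 qpcr = qpcr, noise_scale = noise_scale),
            class = "truth_config")
}

#' Paper-like ground-truth preset
#'
#' Default cohort configuration mimicking the modeled study: patients label
#' for 42 days, healthy controls for 63; controls sit at steady state
#' (loss = production, flat counts) with turnover rates in the range
#' reported for healthy adults; patients carry elevated production rates
#' (folds 6, 3, 8, 4 for naive/memory CD4 and naive/memory CD8 T-cells; 2,
#' 3.5, 5 for naive, Ig-switched and IgM+ memory B-cells) and loss rates
#' raised three- to five-fold, 9.5-fold for naive CD8 T-cells.
#'
#' @param group `"patient"` or `"healthy_control"`.
#' @param individual Identifier.
#' @param subsets Which subsets to include (default all seven).
#' @return A [truth_config].
#' @export
paper_like_config <- function(group = c("patient", "healthy_control"),
                              individual = "ID1", subsets = lk_subsets) {
  group <- match.arg(group)
  base <- list(
    naive_cd4         = list(alphas = 1, rates = 0.0006, X0 = 2.5e5),
    memory_cd4        = list(alphas = c(0.18, 0.82), rates = c(0.03, 0.0006),
                             X0 = 2.0e5),
    naive_cd8         = list(alphas = 1, rates = 0.0005, X0 = 1.3e5),
    memory_cd8        = list(alphas = c(0.20, 0.80), rates = c(0.028, 0.0005),
                             X0 = 1.7e5),
    naive_b           = list(alphas = c(0.06, 0.94), rates = c(0.05, 0.002),
                             X0 = 1.5e5),
    switched_memory_b = list(alphas = c(0.10, 0.90), rates = c(0.06, 0.0025),
                             X0 = 6e4),
    igm_memory_b      = list(alphas = c(0.10, 0.90), rates = c(0.055, 0.003),
                             X0 = 5e4))
  prod_fold <- c(naive_cd4 = 6, memory_cd4 = 3, naive_cd8 = 8,
                 memory_cd8 = 4, naive_b = 2, switched_memory_b = 3.5,
                 igm_memory_b = 5)
  loss_fold <- c(naive_cd4 = 4, memory_cd4 = 3, naive_cd8 = 9.5,
                 memory_cd8 = 4, naive_b = 2.5, switched_memory_b = 3.5,
                 igm_memory_b = 5)
  x0_patient <- c(naive_cd4 = 6e4, memory_cd4 = 1.6e5, naive_cd8 = 1.1e5,
                  memory_cd8 = 2.0e5, naive_b = 2.5e5,
                  switched_memory_b = 3e4, igm_memory_b = 2.5e4)
  subs <- list()
  for (nm in intersect(subsets, names(base))) {
    s <- base[[nm]]
    p_avg <- sum(s$alphas * s$rates)
    if (group == "patient") {
      s$rates <- s$rates * prod_fold[[nm]]
      s$d <- p_avg * loss_fold[[nm]]
      s$X0 <- x0_patient[[nm]]
    } else {
      s$d <- p_avg  # steady state
    }
    subs[[nm]] <- s
  }
  tau <- if (group == "patient") 42 else 63
  qpcr <- list(
    divisions = if (group == "patient") 1.2 else 2.0,
    coding_fraction = 95,
    trec_per_cell = c(naive_cd4 = if (group == "patient") 0.04 else 0.004,
                      naive_cd8 = 0.01))
  truth_config(
    individual = individual, group = group,
    bw = body_water_params(f = 0.015, delta = 0.07, beta = 0.007, tau = tau),
    gran = list(p = 0.3, c = 4.0),
    subsets = subs,
    leukocyte = if (group == "patient") {
      list(intercept = 5.5e6, slope = 800)
    } else {
      list(intercept = 6.0e6, slope = 0)
    },
    qpcr = qpcr)
}

# Label fraction under an explicit, constant source sigma: RK4 integration
# of dN/dt = sigma + (p_div - d) N together with
# dl/dt = (sigma/N + p_div) (c U(t) - l); the per-cell production rate may
# then vary in time through N(t).
.sigma_label_fraction <- function(t_obs, sigma, p_div, d, N0, bw, c_amp,
                                  h = 0.05) {
  deriv <- function(tt, y) {
    c(sigma + (p_div - d) * y[1],
      (sigma / y[1] + p_div) * (c_amp * body_water(tt, bw) - y[2]))
  }
  ts <- sort(unique(c(0, t_obs)))
  y <- c(N0, 0)
  out <- numeric(length(ts)); out[1] <- 0
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
    out[i + 1] <- y[2]
  }
  out[match(t_obs, ts)]
}

.noisy_enrichment <- function(model, sd, scale) {
  if (sd == 0) return(model)
  if (scale == "raw") {
    pmax(model + stats::rnorm(length(model), 0, sd), 0)
  } else {
    sin(.asin_sqrt(model) + stats::rnorm(length(model), 0, sd))^2
  }
}

.noisy_counts <- function(model, sd) {
  if (sd == 0) return(model)
  10^(log10(model) + stats::rnorm(length(model), 0, sd))
}

#' Generate one synthetic individual
#'
#' Produces a complete dataset for one individual from a [truth_config]:
#' urine and granulocyte enrichment, raw (unscaled) subset enrichment,
#' leukocyte and subset counts, and qPCR/TREC tables consistent with the
#' configured division history. Enrichment noise is Gaussian on the
#' arcsin-sqrt scale, count noise Gaussian on the log10 scale; deterministic
#' given `seed`. Subsets carrying an explicit source (`sigma`, `p_div`,
#' `N0`) are simulated by numerical integration of the source-plus-division
#' system instead of the closed-form mixture.
#'
#' @param cfg A [truth_config].
#' @param seed RNG seed.
#' @return List with data frames `enrichment`, `counts`, `qpcr`, `trec`,
#'   and the `truth` config.
#' @export
generate_individual <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "truth_config"))
  withr::with_seed(seed, .generate_individual_impl(cfg))
}

.generate_individual_impl <- function(cfg) {
  bw <- cfg$bw; sch <- cfg$schedule
  sd_e <- cfg$noise$sd_enrichment; sd_c <- cfg$noise$sd_counts
  sd_ct <- if (is.null(cfg$noise$sd_ct)) 0 else cfg$noise$sd_ct
  id <- cfg$individual

  enr <- list()
  enr[["urine"]] <- data.frame(
    individual = id, compartment = "urine", time_days = sch$urine_days,
    enrichment = .noisy_enrichment(body_water(sch$urine_days, bw), sd_e,
                                   cfg$noise_scale),
    scaled_flag = FALSE)
  gran_model <- mono_label_fraction(sch$blood_days, cfg$gran$p, bw, cfg$gran$c)
  enr[["granulocytes"]] <- data.frame(
    individual = id, compartment = "granulocytes", time_days = sch$blood_days,
    enrichment = .noisy_enrichment(gran_model, sd_e, cfg$noise_scale),
    scaled_flag = FALSE)

  counts <- list()
  leuk_true <- cfg$leukocyte$intercept + cfg$leukocyte$slope * sch$blood_days
  leuk_obs <- .noisy_counts(leuk_true, sd_c)

  # subset noise lives on the arcsin-sqrt of the SCALED enrichment (the
  # scale the fitter works on); generate there, then emit raw values
  grid <- seq(min(sch$blood_days), max(sch$blood_days), length.out = 1000)
  m_true <- max(mono_label_fraction(grid, cfg$gran$p, bw, cfg$gran$c))

  for (nm in names(cfg$subsets)) {
    s <- cfg$subsets[[nm]]
    if (is.null(s$sigma)) {
      mix <- kinetic_mixture(s$alphas, s$rates, cfg$gran$c)
      model <- mixture_label_fraction(sch$blood_days, mix, bw)
      p_avg <- average_production_rate(mix)
      x_true <- s$X0 * exp((p_avg - s$d) * sch$blood_days)
    } else {
      model <- .sigma_label_fraction(sch$blood_days, s$sigma, s$p_div, s$d,
                                     s$N0, bw, cfg$gran$c)
      # N(t) solves the linear source-plus-division ODE exactly
      g <- s$p_div - s$d
      x_true <- if (abs(g) < 1e-12) {
        s$N0 + s$sigma * sch$blood_days
      } else {
        (s$N0 + s$sigma / g) * exp(g * sch$blood_days) - s$sigma / g
      }
    }
    enr[[nm]] <- data.frame(
      individual = id, compartment = nm, time_days = sch$blood_days,
      enrichment = m_true * .noisy_enrichment(model / m_true, sd_e,
                                              cfg$noise_scale),
      scaled_flag = FALSE)
    counts[[nm]] <- data.frame(
      individual = id, time_days = sch$blood_days,
      leukocytes_per_ml = leuk_obs, subset = nm,
      subset_count_per_ml = .noisy_counts(x_true, sd_c))
  }

  qpcr <- NULL; trec <- NULL
  if (!is.null(cfg$qpcr)) {
    q <- cfg$qpcr
    # U698-DB01 reference line: arbitrary but fixed assay constants
    ctrl <- c(albumin = 24, coding = 24.6, signal = 25.2)
    alb <- 25 + stats::rnorm(1, 0, sd_ct)
    coding <- alb - ((ctrl[["albumin"]] - ctrl[["coding"]]) +
                       log2(q$coding_fraction / 100)) +
      stats::rnorm(1, 0, sd_ct)
    signal <- coding + (ctrl[["signal"]] - ctrl[["coding"]]) + q$divisions +
      stats::rnorm(1, 0, sd_ct)
    qpcr <- rbind(
      data.frame(individual = id, subset = "naive_b",
                 target = c("albumin", "coding", "signal"),
                 ct_mean = c(alb, coding, signal), control_flag = FALSE),
      data.frame(individual = "U698-DB01", subset = "naive_b",
                 target = c("albumin", "coding", "signal"),
                 ct_mean = unname(ctrl[c("albumin", "coding", "signal")]),
                 control_flag = TRUE))
    if (!is.null(q$trec_per_cell)) {
      cells <- cells_from_dna(100)  # 100 ng input
      trec <- data.frame(
        individual = id, subset = names(q$trec_per_cell),
        trec_copies = round(unname(q$trec_per_cell) * cells),
        cell_equivalents = cells)
    }
  }

  list(enrichment = do.call(rbind, unname(enr)),
       counts = do.call(rbind, unname(counts)),
       qpcr = qpcr, trec = trec, truth = cfg)
}

# Per-individual variation of one subset's kinetics: a common lognormal
# factor on the rates (preserving the mixture shape) and on X0, plus a
# perturbation of the net growth rate r = p - d proportional to the
# subset's turnover, from which the loss rate is rederived. Jittering p and
# d independently would let |r| reach values implying hundred-fold count
# changes over the follow-up year; production and loss are homeostatically
# coupled, and steady-state controls must stay near-flat.
.jitter_config <- function(cfg, jitter_sd, r_jitter_frac = 0.2) {
  if (jitter_sd <= 0) return(cfg)
  for (nm in names(cfg$subsets)) {
    s <- cfg$subsets[[nm]]
    if (is.null(s$sigma)) {
      r0 <- sum(s$alphas * s$rates) - s$d
      s$rates <- pmin(s$rates * exp(stats::rnorm(1, 0, jitter_sd)), 2)
      p_new <- sum(s$alphas * s$rates)
      r_new <- r0 + stats::rnorm(1, 0, r_jitter_frac * p_new)
      s$d <- max(p_new - r_new, 0)
      s$X0 <- s$X0 * exp(stats::rnorm(1, 0, jitter_sd))
      cfg$subsets[[nm]] <- s
    }
  }
  cfg
}

#' Generate a synthetic cohort
#'
#' Patients and healthy controls drawn from two [truth_config] templates,
#' with per-individual lognormal jitter (sd `jitter_sd` on the log scale)
#' applied to subset rates, loss rates and inclusion counts so that
#' individuals differ while group medians track the configured truth.
#' Controls sit at steady state and label for 63 days; patients follow
#' their template. Deterministic given `seed`.
#'
#' @param n_patients,n_controls Group sizes (>= 1).
#' @param seed RNG seed.
#' @param patient_cfg,control_cfg Template [truth_config]s.
#' @param jitter_sd Lognormal sd of the per-individual jitter on rates and
#'   inclusion counts.
#' @param r_jitter_frac Sd of the per-individual jitter on the net growth
#'   rate, as a fraction of the subset's (jittered) production rate; loss
#'   rates are rederived as d = p - r.
#' @return List with combined data frames (`enrichment`, `counts`, `qpcr`,
#'   `trec`, `individuals`), the per-individual `truth` configs, and
#'   `truth_table`: individual x subset true production/loss rates.
#' @export
generate_cohort <- function(n_patients = 6, n_controls = 10, seed = 11,
                            patient_cfg = paper_like_config("patient"),
                            control_cfg = paper_like_config("healthy_control"),
                            jitter_sd = 0.15, r_jitter_frac = 0.2) {
  stopifnot(n_patients >= 1, n_controls >= 1)
  plan <- data.frame(
    individual = c(sprintf("P%02d", seq_len(n_patients)),
                   sprintf("C%02d", seq_len(n_controls))),
    group = rep(c("patient", "healthy_control"), c(n_patients, n_controls)))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1,
                                             nrow(plan)))
  out <- vector("list", nrow(plan))
  truths <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    tmpl <- if (plan$group[i] == "patient") patient_cfg else control_cfg
    tmpl$individual <- plan$individual[i]
    cfg <- withr::with_seed(seeds[i],
                            .jitter_config(tmpl, jitter_sd, r_jitter_frac))
    out[[i]] <- generate_individual(cfg, seed = seeds[i] %% 100000 + 1)
    truths[[i]] <- cfg
  }
  names(truths) <- plan$individual

  truth_rows <- list()
  for (i in seq_len(nrow(plan))) {
    cfg <- truths[[i]]
    for (nm in names(cfg$subsets)) {
      s <- cfg$subsets[[nm]]
      p_true <- if (is.null(s$sigma)) sum(s$alphas * s$rates) else {
        s$sigma / s$N0 + s$p_div
      }
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        individual = cfg$individual, group = cfg$group, subset = nm,
        p_true = p_true, d_true = s$d,
        X0_true = if (is.null(s$sigma)) s$X0 else s$N0)
    }
  }

  list(
    enrichment = do.call(rbind, lapply(out, `[[`, "enrichment")),
    counts = do.call(rbind, lapply(out, `[[`, "counts")),
    qpcr = do.call(rbind, lapply(out, `[[`, "qpcr")),
    trec = do.call(rbind, lapply(out, `[[`, "trec")),
    individuals = data.frame(plan,
                             tau = vapply(truths, function(x) x$bw$tau,
                                          numeric(1))),
    truth = truths,
    truth_table = do.call(rbind, truth_rows))
}
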