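# Maximum-likelihood fitting of body-water, granulocyte and subset kinetics,
# model selection between 1 and 2 subpopulations, residual bootstrap.
#
# Error model: independent homoscedastic Gaussian per data stream on the
# transformed scale (arcsin-sqrt for enrichment, log10 for counts), with the
# stream variance profiled analytically. Minimizing
#   n_e/2 log(RSS_e/n_e) + n_c/2 log(RSS_c/n_c)
# is then exact maximum likelihood; profiling supplies the relative
# weighting of the two streams.

.asin_sqrt <- function(x) asin(sqrt(pmin(pmax(x, 0), 1)))

.clipped_fraction <- function(x) mean(x < 0 | x > 1)

# Variance floored at 1e-16 (sigma 1e-8 on the transformed scale, far below
# measurement precision): keeps the profiled likelihood bounded when one
# stream is fitted exactly, so degenerate noise-free data cannot let one
# stream dominate the joint objective.
.profiled_loglik <- function(rss, n) {
  s2 <- max(rss / n, 1e-16)
  -n / 2 * (log(2 * pi * s2) + 1)
}

# Latin-hypercube start points: one stratified, permuted draw per parameter;
# rate-like parameters sampled log-uniformly.
.lhs_starts <- function(n, lower, upper, log_scale) {
  k <- length(lower)
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    u <- (sample.int(n) - stats::runif(n)) / n
    lo <- lower[j]; hi <- upper[j]
    if (log_scale[j]) {
      lo <- log(lo); hi <- log(hi)
      out[, j] <- exp(lo + u * (hi - lo))
    } else {
      out[, j] <- lo + u * (hi - lo)
    }
  }
  out
}

# Bounded quasi-Newton from multiple starts, two-phase: a short coarse run
# from every start, then full-precision polishing of the best few
# candidates with finite-difference steps scaled to the box (the default
# ndeps of 1e-3 is far too coarse for rates of order 1e-3/d). Returns the
# candidate with the smallest objective (largest loglik) plus diagnostics.
.multistart_optim <- function(objective, starts, lower, upper,
                              coarse_maxit = 40, n_polish = 3) {
  ndeps <- pmax((upper - lower) * 1e-6, 1e-9)
  coarse <- vector("list", nrow(starts))
  values <- rep(NA_real_, nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = coarse_maxit)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    coarse[[i]] <- res
    values[i] <- res$value
  }
  if (all(is.na(values))) {
    stop("fit failure: no multi-start candidate converged to a finite objective")
  }
  best <- NULL
  for (i in utils::head(order(values), n_polish)) {
    if (is.na(values[i])) next
    res <- tryCatch(
      stats::optim(coarse[[i]]$par, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, ndeps = ndeps)),
      error = function(e) coarse[[i]])
    if (!is.finite(res$value)) res <- coarse[[i]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (length(lower) == 1) {
    # 1-D: golden-section refinement around the best candidate
    op <- stats::optimize(function(x) objective(x), c(lower, upper),
                          tol = 1e-10)
    if (op$objective < best$value) {
      best$par <- op$minimum; best$value <- op$objective
    }
    best$all_values <- values
    return(best)
  }
  # ridge escape: quasi-Newton stalls on curved rate/amplitude trade-off
  # valleys; alternate simplex and quasi-Newton steps from the best point
  for (round in 1:2) {
    nm <- tryCatch(
      stats::optim(best$par, function(th) {
        if (any(th < lower) || any(th > upper)) return(1e10)
        objective(th)
      }, method = "Nelder-Mead",
      control = list(maxit = 800, reltol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(nm) && is.finite(nm$value) && nm$value < best$value) {
      best$par <- pmin(pmax(nm$par, lower), upper)
      best$value <- nm$value
    }
    lb <- tryCatch(
      stats::optim(best$par, objective, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, ndeps = ndeps)),
      error = function(e) NULL)
    if (!is.null(lb) && is.finite(lb$value) && lb$value <= best$value) {
      best <- lb
    }
  }
  best$all_values <- values
  best
}

# Single-start refit used inside the bootstrap: warm start, fine gradient.
.optim_refit <- function(start, objective, lower, upper) {
  ndeps <- pmax((upper - lower) * 1e-6, 1e-9)
  stats::optim(start, objective, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 200, ndeps = ndeps))
}

.at_bound <- function(est, lower, upper, tol = 1e-6) {
  (est - lower) < tol * pmax(1, abs(lower)) |
    (upper - est) < tol * pmax(1, abs(upper))
}

#' @export
print.lk_fit <- function(x, ...) {
  cat(sprintf("lymphkin fit (%s)%s\n", x$type,
              if (!is.na(x$n_components)) {
                sprintf(", %d kinetic component(s)", x$n_components)
              } else ""))
  est <- x$estimates
  for (nm in names(est)) {
    line <- sprintf("  %-8s %.5g", nm, est[nm])
    if (!is.null(x$ci95) && nm %in% rownames(x$ci95)) {
      line <- sprintf("%s  [%.5g, %.5g]", line, x$ci95[nm, 1], x$ci95[nm, 2])
    }
    cat(line, "\n")
  }
  cat(sprintf("  log-likelihood: %.4g\n", x$loglik))
  invisible(x)
}

#' Joint fit of body-water and granulocyte enrichment
#'
#' Estimates the body-water curve (f, delta, beta) and the granulocyte
#' kinetics (p_gran and the amplification factor c) for one individual by
#' maximizing a Gaussian likelihood on arcsin-sqrt transformed urine and
#' granulocyte enrichment simultaneously, from 20 Latin-hypercube
#' multi-starts. The label-administration end `tau` is fixed by the study
#' protocol, not estimated. The scaling maximum M — the fitted granulocyte
#' curve's maximum over the granulocyte observation window — is attached for
#' downstream subset scaling.
#'
#' @param urine [enrichment_series] of compartment `urine` (>= 4 points).
#' @param gran [enrichment_series] of compartment `granulocytes`, unscaled
#'   (>= 4 points).
#' @param tau End of label administration (days); 42 for the patient
#'   protocol, 63 for the healthy-control protocol.
#' @param n_starts Number of multi-start candidates.
#' @param seed Seed for the multi-start draw (deterministic fits).
#' @return An `lk_fit` of type `"bodywater"` with `params$bw`,
#'   `params$p_gran`, `params$c_amp` and `params$M`.
#' @export
fit_body_water_and_granulocytes <- function(urine, gran, tau = 42,
                                            n_starts = 20, seed = 1) {
  stopifnot(inherits(urine, "enrichment_series"),
            inherits(gran, "enrichment_series"))
  if (urine$compartment != "urine") stop("urine series must have compartment 'urine'")
  if (gran$compartment != "granulocytes") {
    stop("gran series must have compartment 'granulocytes'")
  }
  if (gran$scaled) stop("granulocyte series must be unscaled")
  if (length(urine$times) < 4) stop("need >= 4 urine points")
  if (length(gran$times) < 4) stop("need >= 4 granulocyte points")

  t_u <- urine$times; y_u <- .asin_sqrt(urine$values)
  t_g <- gran$times;  y_g <- .asin_sqrt(gran$values)
  n_u <- length(t_u); n_g <- length(t_g)

  #            f      delta  beta   p_gran c_amp
  lower <- c(1e-4,  5e-3,  0,     1e-2,  0.5)
  upper <- c(0.1,   0.5,   0.1,   2,     10)
  log_scale <- c(FALSE, TRUE, FALSE, TRUE, TRUE)

  objective <- function(theta) {
    r_u <- y_u - .asin_sqrt(.bw_core(t_u, theta[1], theta[2], theta[3], tau))
    r_g <- y_g - .asin_sqrt(.mono_core(t_g, theta[4], theta[1], theta[2],
                                       theta[3], tau, theta[5]))
    n_u / 2 * log(max(sum(r_u^2) / n_u, 1e-16)) +
      n_g / 2 * log(max(sum(r_g^2) / n_g, 1e-16))
  }

  best <- withr::with_seed(seed, {
    starts <- .lhs_starts(n_starts, lower, upper, log_scale)
    # one data-driven start: plateau and ramp-up read off the urine series,
    # amplification from the granulocyte maximum over the urine plateau
    f0 <- min(max(max(urine$values), lower[1] * 2), upper[1])
    b0 <- min(max(urine$values[1], lower[3]), upper[3])
    c0 <- min(max(max(gran$values) / max(f0, 1e-4), lower[5] * 1.01), upper[5])
    starts <- rbind(starts, c(f0, 0.07, b0, 0.25, c0))
    .multistart_optim(objective, starts, lower, upper)
  })

  theta <- best$par
  bw <- body_water_params(theta[1], theta[2], theta[3], tau)
  p_gran <- theta[4]; c_amp <- theta[5]
  grid <- seq(min(t_g), max(t_g), length.out = 1000)
  M <- max(mono_label_fraction(grid, p_gran, bw, c_amp))
  if (M <= 0) stop("invalid fit: granulocyte maximum <= 0")

  fit_u <- .asin_sqrt(body_water(t_u, bw))
  fit_g <- .asin_sqrt(mono_label_fraction(t_g, p_gran, bw, c_amp))
  r_u <- y_u - fit_u; r_g <- y_g - fit_g
  rss_u <- sum(r_u^2); rss_g <- sum(r_g^2)

  structure(list(
    type = "bodywater",
    individual = urine$individual,
    params = list(bw = bw, p_gran = p_gran, c_amp = c_amp, M = M),
    estimates = c(f = bw$f, delta = bw$delta, beta = bw$beta,
                  p_gran = p_gran, c_amp = c_amp, M = M),
    n_components = NA_integer_,
    loglik = .profiled_loglik(rss_u, n_u) + .profiled_loglik(rss_g, n_g),
    rss = list(urine = rss_u, granulocytes = rss_g),
    residuals = list(urine = r_u, granulocytes = r_g),
    fitted_trans = list(urine = fit_u, granulocytes = fit_g),
    clipped_fraction = .clipped_fraction(c(urine$values, gran$values)),
    at_bound = .at_bound(theta, lower, upper),
    objective_value = best$value,
    multistart_values = best$all_values,
    convergence = best$convergence,
    data = list(urine = urine, gran = gran, tau = tau),
    bounds = list(lower = lower, upper = upper, log_scale = log_scale),
    ci95 = NULL, n_boot = 0L, seed = seed
  ), class = "lk_fit")
}

# Scaled enrichment prediction for a (possibly 2-component) subset.
.subset_pred_enr <- function(t, alphas, rates, c_amp, bw, M) {
  out <- 0
  for (i in seq_along(alphas)) {
    out <- out + alphas[i] * .mono_core(t, rates[i], bw$f, bw$delta,
                                        bw$beta, bw$tau, c_amp)
  }
  out / M
}

# theta layout (enrichment parameters only): k=1 -> (log10 p1)
#                                            k=2 -> (log10 p1, log10 p2, alpha1)
# The count-model parameters (d, X0) are conditionally linear given the
# average production rate and are profiled out analytically (.profile_counts),
# which removes the zero-residual degeneracy of joint search and cuts the
# search to 1 or 3 dimensions.
.subset_unpack <- function(theta, k) {
  if (k == 1L) {
    list(alphas = 1, rates = 10^theta[1])
  } else {
    list(alphas = c(theta[3], 1 - theta[3]), rates = 10^theta[1:2])
  }
}

# Given p_avg, the log10-count model y = lx0 + (p_avg - d) t / ln10 is
# linear in (lx0, slope); OLS gives the conditional ML. The loss rate is
# bounded to [0, 2]/d: outside, the slope is pinned and only the intercept
# profiled. Returns d, lx0, rss and a clipped flag.
.profile_counts <- function(p_avg, t_c, y_c, sxx, t_bar, y_bar) {
  b_free <- sum((t_c - t_bar) * (y_c - y_bar)) / sxx
  d <- p_avg - b_free * log(10)
  clipped <- FALSE
  if (d < 0 || d > 2) {
    d <- min(max(d, 0), 2)
    clipped <- TRUE
  }
  b <- (p_avg - d) / log(10)
  lx0 <- y_bar - b * t_bar
  rss <- sum((y_c - lx0 - b * t_c)^2)
  list(d = d, lx0 = lx0, rss = rss, clipped = clipped)
}

.subset_objective <- function(t_e, y_e, t_c, y_c, k, c_amp, bw, M) {
  n_e <- length(t_e); n_c <- length(t_c)
  t_bar <- mean(t_c); y_bar <- mean(y_c)
  sxx <- sum((t_c - t_bar)^2)
  function(theta) {
    u <- .subset_unpack(theta, k)
    pred_e <- .subset_pred_enr(t_e, u$alphas, u$rates, c_amp, bw, M)
    r_e <- y_e - .asin_sqrt(pred_e)
    p_avg <- sum(u$alphas * u$rates)
    pc <- .profile_counts(p_avg, t_c, y_c, sxx, t_bar, y_bar)
    n_e / 2 * log(max(sum(r_e^2) / n_e, 1e-16)) +
      n_c / 2 * log(max(pc$rss / n_c, 1e-16))
  }
}

.subset_bounds <- function(k) {
  lp_lo <- -5; lp_hi <- log10(2)
  if (k == 1L) {
    list(lower = lp_lo, upper = lp_hi, log_scale = FALSE)
  } else {
    list(lower = c(lp_lo, lp_lo, 0), upper = c(lp_hi, lp_hi, 1),
         log_scale = rep(FALSE, 3))
  }
}

#' Joint fit of subset enrichment and normalized cell numbers
#'
#' For one lymphocyte subset of one individual, estimates the kinetic
#' mixture (alpha_i, p_i), the loss rate d and the inclusion-time cell count
#' X0 by maximizing the sum of two profiled Gaussian log-likelihoods:
#' scaled enrichment residuals of the multi-exponential labeling curve on
#' the arcsin-sqrt scale, and normalized-count residuals of
#' `X0 exp((p - d) t)` on the log10 scale, where `p = sum(alpha_i p_i)` is
#' the average per-cell production rate. The body-water curve, amplification
#' factor and scaling maximum M are fixed from the upstream fit.
#'
#' @param enrichment Scaled [enrichment_series] of the subset (>= 6 points;
#'   >= 8 for a 2-component fit).
#' @param counts Data frame with columns `time_days` and `count`
#'   (normalized cells per ml, > 0; >= 4 rows).
#' @param bw Fixed [body_water_params] from the body-water fit.
#' @param c_amp Fixed amplification factor.
#' @param M Fixed granulocyte scaling maximum.
#' @param n_components 1 or 2 kinetic subpopulations.
#' @param n_starts Number of Latin-hypercube multi-starts.
#' @param seed Seed for the multi-start draw.
#' @return An `lk_fit` of type `"subset"`; `estimates` reports the average
#'   production rate `p`, the component rates/fractions, loss rate `d`, net
#'   growth rate `r = p - d` and `X0`. Rate parameters pinned at a box bound
#'   are flagged in `at_bound`.
#' @export
fit_subset <- function(enrichment, counts, bw, c_amp, M,
                       n_components = 1L, n_starts = 20, seed = 1,
                       extra_starts = NULL) {
  stopifnot(inherits(enrichment, "enrichment_series"),
            inherits(bw, "body_water_params"),
            is.data.frame(counts),
            all(c("time_days", "count") %in% names(counts)))
  if (!enrichment$scaled) stop("enrichment series must be scaled (granulocyte_scale)")
  k <- as.integer(n_components)
  if (!k %in% c(1L, 2L)) stop("n_components must be 1 or 2")
  n_e <- length(enrichment$times)
  if (n_e < 6) stop("need >= 6 enrichment points")
  if (k == 2L && n_e < 8) {
    stop("2-component fit refused: under-identified with < 8 enrichment points")
  }
  counts <- counts[is.finite(counts$count) & counts$count > 0, , drop = FALSE]
  if (nrow(counts) < 4) stop("need >= 4 positive count points")
  if (!is.finite(M) || M <= 0) stop("M must be > 0")

  t_e <- enrichment$times; y_e <- .asin_sqrt(enrichment$values)
  t_c <- counts$time_days; y_c <- log10(counts$count)
  b <- .subset_bounds(k)
  objective <- .subset_objective(t_e, y_e, t_c, y_c, k, c_amp, bw, M)

  # structured rate-grid starts alongside the Latin-hypercube draws
  extra <- if (k == 1L) {
    matrix(log10(c(0.001, 0.01, 0.05, 0.3)), ncol = 1)
  } else {
    grid <- expand.grid(p1 = c(0.05, 0.2, 1), p2 = c(0.001, 0.008),
                        a1 = c(0.12, 0.35))
    cbind(log10(grid$p1), log10(grid$p2), grid$a1)
  }
  best <- withr::with_seed(seed, {
    starts <- rbind(.lhs_starts(n_starts, b$lower, b$upper, b$log_scale),
                    extra, extra_starts)
    .multistart_optim(objective, starts, b$lower, b$upper)
  })

  .subset_fit_result(best, enrichment, counts, bw, c_amp, M, k, b, seed)
}

# Assemble an lk_fit from an optimizer result (shared with the bootstrap).
.subset_fit_result <- function(best, enrichment, counts, bw, c_amp, M, k, b,
                               seed) {
  theta <- best$par
  u <- .subset_unpack(theta, k)
  mix <- kinetic_mixture(u$alphas, u$rates, c_amp)
  p_avg <- average_production_rate(mix)

  t_e <- enrichment$times; y_e <- .asin_sqrt(enrichment$values)
  t_c <- counts$time_days; y_c <- log10(counts$count)
  t_bar <- mean(t_c); y_bar <- mean(y_c)
  pc <- .profile_counts(p_avg, t_c, y_c, sum((t_c - t_bar)^2), t_bar, y_bar)
  d <- pc$d; X0 <- 10^pc$lx0

  fit_e <- .asin_sqrt(.subset_pred_enr(t_e, mix$alphas, mix$rates, c_amp, bw, M))
  fit_c <- pc$lx0 + (p_avg - d) * t_c / log(10)
  r_e <- y_e - fit_e; r_c <- y_c - fit_c
  rss_e <- sum(r_e^2); rss_c <- sum(r_c^2)

  est <- c(p = p_avg)
  for (i in seq_len(k)) est[paste0("p", i)] <- mix$rates[i]
  for (i in seq_len(k)) est[paste0("alpha", i)] <- mix$alphas[i]
  est["d"] <- d; est["r"] <- p_avg - d; est["X0"] <- X0

  structure(list(
    type = "subset",
    individual = enrichment$individual,
    subset = enrichment$compartment,
    params = list(mix = mix, d = d, X0 = X0, bw = bw, c_amp = c_amp, M = M),
    estimates = est,
    n_components = k,
    loglik = .profiled_loglik(rss_e, length(t_e)) +
      .profiled_loglik(rss_c, length(t_c)),
    rss = list(enrichment = rss_e, counts = rss_c),
    residuals = list(enrichment = r_e, counts = r_c),
    fitted_trans = list(enrichment = fit_e, counts = fit_c),
    clipped_fraction = .clipped_fraction(enrichment$values),
    at_bound = .at_bound(best$par, b$lower, b$upper),
    d_clipped = pc$clipped,
    objective_value = best$value,
    multistart_values = best$all_values,
    convergence = best$convergence,
    data = list(enrichment = enrichment, counts = counts),
    bounds = b,
    ci95 = NULL, n_boot = 0L, seed = seed
  ), class = "lk_fit")
}

#' Choose between one and two kinetic subpopulations
#'
#' Extra-sum-of-squares F-test on the enrichment residual sum of squares:
#' the 2-component model spends two extra parameters (a second rate and its
#' fraction); 2 is returned iff the test rejects at the 0.05 level. If the
#' 2-component fit has the larger RSS (optimizer failure on the nested
#' model), 1 is returned with a warning.
#'
#' @param fit1,fit2 `lk_fit` objects from [fit_subset] with 1 and 2
#'   components, fitted to identical data.
#' @return 1 or 2, with the F-test p-value attached as attribute `p_value`.
#' @export
select_components <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "lk_fit"), inherits(fit2, "lk_fit"),
            fit1$n_components == 1L, fit2$n_components == 2L)
  if (!isTRUE(all.equal(fit1$data$enrichment$values,
                        fit2$data$enrichment$values)) ||
      !isTRUE(all.equal(fit1$data$enrichment$times,
                        fit2$data$enrichment$times))) {
    stop("fits must be on identical data")
  }
  rss1 <- fit1$rss$enrichment; rss2 <- fit2$rss$enrichment
  n_e <- length(fit1$data$enrichment$times)
  if (rss2 > rss1 + max(1e-12, 1e-6 * rss1)) {
    warning("2-component fit worse than 1-component (optimizer failure); selecting 1")
    return(structure(1L, p_value = 1))
  }
  rss2 <- min(rss2, rss1)  # floor-level numerical ties count as no improvement
  df2 <- n_e - 3L  # 2-component enrichment curve has 3 free parameters
  f_stat <- ((rss1 - rss2) / 2) / (rss2 / df2)
  p_val <- stats::pf(f_stat, 2, df2, lower.tail = FALSE)
  structure(if (p_val < 0.05) 2L else 1L, p_value = p_val)
}

#' Fit a subset with automatic component selection
#'
#' Runs [fit_subset] with 1 and (data permitting) 2 components and returns
#' the fit chosen by [select_components].
#'
#' @inheritParams fit_subset
#' @return The selected `lk_fit`, with `selection` recording the F-test
#'   p-value and the candidates' enrichment RSS.
#' @export
fit_subset_auto <- function(enrichment, counts, bw, c_amp, M,
                            n_starts = 20, seed = 1) {
  fit1 <- fit_subset(enrichment, counts, bw, c_amp, M, 1L, n_starts, seed)
  if (length(enrichment$times) < 8) {
    fit1$selection <- list(chosen = 1L, p_value = NA_real_,
                           reason = "too few points for 2 components")
    return(fit1)
  }
  # seed the 2-component search with the 1-component optimum so the nested
  # model can never genuinely fit worse
  lp1 <- log10(max(fit1$params$mix$rates[1], 1e-5))
  warm <- rbind(c(lp1, lp1, 0.5), c(lp1, -3, 0.99), c(0, lp1, 0.01))
  fit2 <- fit_subset(enrichment, counts, bw, c_amp, M, 2L, n_starts, seed,
                     extra_starts = warm)
  choice <- select_components(fit1, fit2)
  out <- if (choice == 2L) fit2 else fit1
  out$selection <- list(chosen = as.integer(choice),
                        p_value = attr(choice, "p_value"),
                        rss1 = fit1$rss$enrichment,
                        rss2 = fit2$rss$enrichment)
  out
}

# Leverage of the transformed enrichment observations: diagonal of the hat
# matrix of the linearized model at the optimum (finite-difference
# Jacobian over the 1 or 3 enrichment parameters).
.enr_leverage <- function(fit) {
  t_e <- fit$data$enrichment$times
  k <- fit$n_components
  theta <- if (k == 1L) {
    log10(max(fit$params$mix$rates[1], 1e-10))
  } else {
    c(log10(pmax(fit$params$mix$rates, 1e-10)), fit$params$mix$alphas[1])
  }
  pred <- function(th) {
    u <- .subset_unpack(th, k)
    .asin_sqrt(.subset_pred_enr(t_e, u$alphas, u$rates, fit$params$c_amp,
                                fit$params$bw, fit$params$M))
  }
  jac <- vapply(seq_along(theta), function(j) {
    h <- 1e-5
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    (pred(tp) - pred(tm)) / (2 * h)
  }, numeric(length(t_e)))
  jac <- matrix(jac, nrow = length(t_e))
  xtx <- crossprod(jac)
  inv <- tryCatch(solve(xtx + diag(1e-12, ncol(jac))),
                  error = function(e) NULL)
  if (is.null(inv)) return(rep(length(theta) / length(t_e), length(t_e)))
  pmin(pmax(rowSums((jac %*% inv) * jac), 0), 0.99)
}

# One residual-bootstrap replicate for a subset fit: resample the two
# residual streams independently, rebuild data on the raw scales, refit from
# the point estimate.
.boot_refit_subset <- function(fit, r_e, r_c) {
  enr0 <- fit$data$enrichment
  n_e <- length(fit$fitted_trans$enrichment)
  n_c <- length(fit$fitted_trans$counts)
  new_e <- fit$fitted_trans$enrichment + sample(c(r_e, -r_e), n_e,
                                                replace = TRUE)
  new_c <- fit$fitted_trans$counts + sample(c(r_c, -r_c), n_c,
                                            replace = TRUE)
  vals <- sin(pmin(pmax(new_e, 0), pi / 2))^2
  enr <- enrichment_series(enr0$individual, enr0$compartment, enr0$times,
                           vals, scaled = TRUE)
  cnt <- data.frame(time_days = fit$data$counts$time_days, count = 10^new_c)
  t_e <- enr$times; y_e <- .asin_sqrt(enr$values)
  t_c <- cnt$time_days; y_c <- log10(cnt$count)
  objective <- .subset_objective(t_e, y_e, t_c, y_c, fit$n_components,
                                 fit$params$c_amp, fit$params$bw, fit$params$M)
  start <- if (fit$n_components == 1L) {
    log10(max(fit$params$mix$rates[1], 1e-5))
  } else {
    c(log10(pmax(fit$params$mix$rates, 1e-5)), fit$params$mix$alphas[1])
  }
  start <- pmin(pmax(start, fit$bounds$lower), fit$bounds$upper)
  res <- .optim_refit(start, objective, fit$bounds$lower, fit$bounds$upper)
  bf <- .subset_fit_result(res, enr, cnt, fit$params$bw, fit$params$c_amp,
                           fit$params$M, fit$n_components, fit$bounds,
                           NA_integer_)
  bf$estimates
}

.boot_refit_bodywater <- function(fit, r_u, r_g) {
  u0 <- fit$data$urine; g0 <- fit$data$gran
  n_u <- length(r_u); n_g <- length(r_g)
  new_u <- fit$fitted_trans$urine + sample(c(r_u, -r_u), n_u, replace = TRUE)
  new_g <- fit$fitted_trans$granulocytes + sample(c(r_g, -r_g), n_g,
                                                  replace = TRUE)
  urine <- enrichment_series(u0$individual, "urine", u0$times,
                             sin(pmin(pmax(new_u, 0), pi / 2))^2)
  gran <- enrichment_series(g0$individual, "granulocytes", g0$times,
                            sin(pmin(pmax(new_g, 0), pi / 2))^2)
  t_u <- urine$times; y_u <- .asin_sqrt(urine$values)
  t_g <- gran$times;  y_g <- .asin_sqrt(gran$values)
  tau <- fit$data$tau
  objective <- function(theta) {
    ru <- y_u - .asin_sqrt(.bw_core(t_u, theta[1], theta[2], theta[3], tau))
    rg <- y_g - .asin_sqrt(.mono_core(t_g, theta[4], theta[1], theta[2],
                                      theta[3], tau, theta[5]))
    length(t_u) / 2 * log(max(sum(ru^2) / length(t_u), 1e-16)) +
      length(t_g) / 2 * log(max(sum(rg^2) / length(t_g), 1e-16))
  }
  start <- pmin(pmax(unname(fit$estimates[1:5]), fit$bounds$lower),
                fit$bounds$upper)
  res <- .optim_refit(start, objective, fit$bounds$lower, fit$bounds$upper)
  theta <- res$par
  grid <- seq(min(t_g), max(t_g), length.out = 1000)
  M <- max(.mono_core(grid, theta[4], theta[1], theta[2], theta[3], tau,
                      theta[5]))
  c(f = theta[1], delta = theta[2], beta = theta[3],
    p_gran = theta[4], c_amp = theta[5], M = M)
}

#' Residual-bootstrap confidence intervals
#'
#' Resamples the per-stream residuals (enrichment and counts, or urine and
#' granulocytes) independently with replacement on their transformed scales,
#' rebuilds the data, refits from the point estimate, and reports 2.5/97.5
#' percentile intervals for every reported parameter. Fitted residuals are
#' underdispersed, so they are rescaled before resampling: subset fits use
#' per-point leverage factors 1/sqrt(1 - h_ii) from the linearized model at
#' the optimum, body-water fits the global sqrt(n/(n - k)) correction. The
#' residual pool is symmetrized (each residual enters with both signs):
#' the error model is symmetric Gaussian, and with ~10 residuals per stream
#' the accidental skew of the raw pool otherwise shifts the percentile
#' endpoints and costs real coverage. The number of components of a subset
#' fit is held fixed across replicates. Deterministic given `seed`.
#'
#' @param fit An `lk_fit` from [fit_subset] or
#'   [fit_body_water_and_granulocytes] (data are carried inside the fit).
#' @param n_boot Number of bootstrap replicates (>= 100 for reported CIs).
#' @param seed RNG seed.
#' @return The fit with `ci95` (matrix, one row per parameter), `n_boot`,
#'   `boot_seed` and `n_boot_failed` filled in.
#' @export
bootstrap_ci <- function(fit, n_boot = 500, seed = 1) {
  stopifnot(inherits(fit, "lk_fit"))
  if (n_boot < 100) stop("n_boot must be >= 100")
  if (fit$type == "subset") {
    r1 <- fit$residuals$enrichment / sqrt(pmax(1 - .enr_leverage(fit), 0.1))
    t_c <- fit$data$counts$time_days
    h_c <- 1 / length(t_c) + (t_c - mean(t_c))^2 / sum((t_c - mean(t_c))^2)
    r2 <- fit$residuals$counts / sqrt(pmax(1 - h_c, 0.1))
    refit <- function() .boot_refit_subset(fit, r1, r2)
  } else {
    n_u <- length(fit$residuals$urine)
    n_g <- length(fit$residuals$granulocytes)
    r1 <- fit$residuals$urine * sqrt(n_u / max(n_u - 3L, 1))
    r2 <- fit$residuals$granulocytes * sqrt(n_g / max(n_g - 2L, 1))
    refit <- function() .boot_refit_bodywater(fit, r1, r2)
  }
  draws <- withr::with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      tryCatch(refit(), error = function(e) NULL)
    })
  })
  failed <- vapply(draws, is.null, logical(1))
  if (mean(failed) > 0.2) {
    stop(sprintf("bootstrap failure: %d/%d refits failed", sum(failed), n_boot))
  }
  mat <- do.call(rbind, draws[!failed])
  common <- intersect(names(fit$estimates), colnames(mat))
  ci <- t(apply(mat[, common, drop = FALSE], 2, stats::quantile,
                probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  # percentile intervals are widened, if needed, to bracket the point estimate
  ci[, 1] <- pmin(ci[, 1], fit$estimates[common])
  ci[, 2] <- pmax(ci[, 2], fit$estimates[common])
  fit$ci95 <- ci
  fit$n_boot <- as.integer(n_boot)
  fit$boot_seed <- seed
  fit$n_boot_failed <- sum(failed)
  fit
}
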