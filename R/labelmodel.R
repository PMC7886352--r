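# Closed-form label kinetics: body-water curve, mono-exponential label
# fraction, kinetic mixtures, granulocyte scaling, isotope calibration.

#' Recognized cell compartments
#'
#' Compartment labels accepted throughout the package. `urine` holds
#' body-water enrichment; `granulocytes` anchor the maximal attainable DNA
#' enrichment; the remaining entries are sorted lymphocyte subsets plus the
#' baseline PBMC sample.
#'
#' @format Character vector.
#' @export
lk_compartments <- c(
  "urine", "granulocytes",
  "naive_cd4", "memory_cd4", "naive_cd8", "memory_cd8",
  "naive_b", "switched_memory_b", "igm_memory_b",
  "pbmc_baseline"
)

#' Lymphocyte subsets with kinetic fits
#' @format Character vector, subset of [lk_compartments].
#' @export
lk_subsets <- c(
  "naive_cd4", "memory_cd4", "naive_cd8", "memory_cd8",
  "naive_b", "switched_memory_b", "igm_memory_b"
)

#' Body-water enrichment parameters
#'
#' Parameters of the deuterium fraction in body water, U(t): an oral ramp-up
#' dose brings body water to enrichment `beta` on day 0; daily maintenance
#' doses drive it towards the plateau `f` at turnover rate `delta`; after
#' label intake stops at day `tau` the label washes out exponentially at the
#' same rate.
#'
#' @param f Asymptotic body-water enrichment (fraction, 0-1).
#' @param delta Body-water turnover rate (per day, > 0).
#' @param beta Enrichment attained by the ramp-up dose (fraction, 0-1).
#' @param tau End of label administration (days, > 0). 42 for the six-week
#'   patient protocol, 63 for the nine-week healthy-control protocol.
#' @return Object of class `body_water_params`.
#' @export
body_water_params <- function(f, delta, beta, tau) {
  stopifnot(length(f) == 1, length(delta) == 1, length(beta) == 1,
            length(tau) == 1)
  if (!is.finite(f) || f < 0 || f > 1) stop("f must be in [0, 1]")
  if (!is.finite(beta) || beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (!is.finite(delta) || delta <= 0) stop("delta must be > 0")
  if (is.na(tau) || tau <= 0) stop("tau must be > 0")
  structure(list(f = f, delta = delta, beta = beta, tau = tau),
            class = "body_water_params")
}

#' @export
print.body_water_params <- function(x, ...) {
  cat(sprintf(
    "Body-water enrichment curve: f = %.4g, delta = %.4g /d, beta = %.4g, tau = %g d\n",
    x$f, x$delta, x$beta, x$tau))
  invisible(x)
}

#' Body-water enrichment U(t)
#'
#' Piecewise curve: `U(t) = f (1 - e^(-delta t)) + beta e^(-delta t)` while
#' label is taken (t <= tau), exponential washout `U(tau) e^(-delta (t-tau))`
#' afterwards. Continuous at `tau`.
#'
#' @param t Time since first label intake (days, >= 0); vectorized.
#' @param params A [body_water_params] object.
#' @return Enrichment fraction, same length as `t`.
#' @export
body_water <- function(t, params) {
  stopifnot(inherits(params, "body_water_params"))
  if (any(t < 0)) stop("t must be >= 0")
  .bw_core(t, params$f, params$delta, params$beta, params$tau)
}

# (e^(h t) - 1) / h with the h -> 0 limit t; used for the p = delta
# degenerate case of the label integral.
.expm1_ratio <- function(h, t) {
  small <- abs(h * t) < 1e-9
  out <- numeric(length(t))
  ht <- h * t
  out[small] <- t[small] * (1 + ht[small] / 2 + ht[small]^2 / 6)
  out[!small] <- expm1(ht[!small]) / h
  out
}

# Validation-free vectorized cores, shared by the user-facing functions and
# the optimizer inner loops (where call overhead dominates).
.bw_core <- function(t, f, delta, beta, tau) {
  up <- f * (1 - exp(-delta * t)) + beta * exp(-delta * t)
  if (is.infinite(tau)) return(up)
  late <- t > tau
  if (any(late)) {
    u_tau <- f * (1 - exp(-delta * tau)) + beta * exp(-delta * tau)
    up[late] <- u_tau * exp(-delta * (t[late] - tau))
  }
  up
}

.mono_core <- function(t, p, f, delta, beta, tau, c_amp) {
  if (p == 0) return(rep(0, length(t)))
  ept <- exp(-p * t)
  out <- c_amp * (f * (1 - ept) +
                    p * (beta - f) * ept * .expm1_ratio(p - delta, t))
  late <- t > tau
  if (!is.infinite(tau) && any(late)) {
    edt <- exp(-delta * tau); eptau <- exp(-p * tau)
    u_tau <- f * (1 - edt) + beta * edt
    l_tau <- c_amp * (f * (1 - eptau) +
                        p * (beta - f) * eptau * .expm1_ratio(p - delta, tau))
    dt <- t[late] - tau
    epd <- exp(-p * dt)
    out[late] <- l_tau * epd +
      c_amp * p * u_tau * epd * .expm1_ratio(p - delta, dt)
  }
  out
}

#' Mono-exponential label fraction l(t)
#'
#' Solves `dl/dt = p (c U(t) - l)`, `l(0) = 0`, in closed form: the fraction
#' of labeled DNA in a kinetically homogeneous population with per-cell
#' production rate `p`, given body-water availability `U(t)` and
#' amplification factor `c`. The loss rate cancels out of the fraction and
#' does not appear. The `p = delta` singularity is evaluated via its analytic
#' limit.
#'
#' @param t Days since start of labeling (>= 0); vectorized.
#' @param p Per-cell production rate (per day, >= 0).
#' @param bw A [body_water_params] object.
#' @param c_amp Amplification factor relating body-water to maximal DNA
#'   enrichment (> 0). Default 1 gives the fraction scaled to body water.
#' @return Label fraction, same length as `t`.
#' @export
mono_label_fraction <- function(t, p, bw, c_amp = 1) {
  stopifnot(inherits(bw, "body_water_params"))
  if (length(p) != 1 || !is.finite(p) || p < 0) stop("p must be a single value >= 0")
  if (any(t < 0)) stop("t must be >= 0")
  if (!is.finite(c_amp) || c_amp <= 0) stop("c_amp must be > 0")
  # uptake: l(t) = c [ f (1 - e^{-pt}) + p (beta - f) e^{-pt} R(t) ] with
  # R(t) = (e^{(p-delta) t} - 1)/(p - delta); after tau the integral
  # continues against the washout curve from l(tau).
  .mono_core(t, p, bw$f, bw$delta, bw$beta, bw$tau, c_amp)
}

#' Kinetic mixture of subpopulations
#'
#' A cell subset made of `i = 1..k` subpopulations, subpopulation `i` holding
#' a fraction `alphas[i]` of the cells and turning over at production rate
#' `rates[i]` per day (kinetic heterogeneity). Components are stored in
#' decreasing rate order to resolve label switching; one or two components
#' are supported.
#'
#' @param alphas Component fractions (non-negative, summing to 1).
#' @param rates Component production rates (per day, >= 0).
#' @param c_amp Amplification factor (> 0).
#' @return Object of class `kinetic_mixture`.
#' @export
kinetic_mixture <- function(alphas, rates, c_amp = 1) {
  if (length(alphas) != length(rates)) stop("alphas and rates must match in length")
  if (!length(alphas) %in% c(1L, 2L)) stop("number of components must be 1 or 2")
  if (any(alphas < 0)) stop("alphas must be >= 0")
  if (abs(sum(alphas) - 1) > 1e-12) stop("alphas must sum to 1")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (!is.finite(c_amp) || c_amp <= 0) stop("c_amp must be > 0")
  ord <- order(rates, decreasing = TRUE)
  structure(list(alphas = alphas[ord], rates = rates[ord], c_amp = c_amp),
            class = "kinetic_mixture")
}

#' @export
print.kinetic_mixture <- function(x, ...) {
  cat(sprintf("Kinetic mixture (%d component%s), c = %.3g\n",
              length(x$alphas), if (length(x$alphas) > 1) "s" else "", x$c_amp))
  for (i in seq_along(x$alphas)) {
    cat(sprintf("  alpha = %.4g, p = %.4g /d\n", x$alphas[i], x$rates[i]))
  }
  cat(sprintf("  average production rate: %.4g /d\n", average_production_rate(x)))
  invisible(x)
}

#' Multi-exponential label fraction
#'
#' Label fraction of a heterogeneous subset: the alpha-weighted sum of
#' [mono_label_fraction] over the mixture components.
#'
#' @param t Days since start of labeling; vectorized.
#' @param mix A [kinetic_mixture].
#' @param bw A [body_water_params] object.
#' @return Label fraction, same length as `t`.
#' @export
mixture_label_fraction <- function(t, mix, bw) {
  stopifnot(inherits(mix, "kinetic_mixture"))
  out <- numeric(length(t))
  for (i in seq_along(mix$alphas)) {
    out <- out + mix$alphas[i] * mono_label_fraction(t, mix$rates[i], bw, mix$c_amp)
  }
  out
}

#' Average per-cell production rate of a mixture
#'
#' `p = sum_i alpha_i p_i`, the quantity reported per subset.
#'
#' @param mix A [kinetic_mixture].
#' @return Rate (per day).
#' @export
average_production_rate <- function(mix) {
  stopifnot(inherits(mix, "kinetic_mixture"))
  sum(mix$alphas * mix$rates)
}

#' Time-stamped enrichment observations
#'
#' One individual x compartment series of deuterium enrichment measurements.
#'
#' @param individual Identifier.
#' @param compartment One of [lk_compartments].
#' @param times Days since start of labeling, strictly increasing, >= 0.
#' @param values Enrichment as a fraction, >= 0. Scaled values may slightly
#'   exceed 1 through noise; a sanity bound of 1.5 is enforced.
#' @param scaled Whether values are normalized to the granulocyte maximum.
#' @return Object of class `enrichment_series`.
#' @export
enrichment_series <- function(individual, compartment, times, values,
                              scaled = FALSE) {
  if (!compartment %in% lk_compartments) {
    stop("unknown compartment: ", compartment)
  }
  if (length(times) != length(values)) stop("times and values must match")
  if (any(times < 0)) stop("times must be >= 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(values < 0)) stop("values must be >= 0")
  if (scaled && any(values > 1.5)) stop("scaled values above sanity bound 1.5")
  structure(list(individual = as.character(individual),
                 compartment = compartment,
                 times = as.numeric(times), values = as.numeric(values),
                 scaled = isTRUE(scaled)),
            class = "enrichment_series")
}

#' @export
print.enrichment_series <- function(x, ...) {
  cat(sprintf("Enrichment series: %s / %s, %d points over %.0f-%.0f d%s\n",
              x$individual, x$compartment, length(x$times),
              min(x$times), max(x$times),
              if (x$scaled) " (scaled)" else ""))
  invisible(x)
}

#' Scale a series to the granulocyte maximum
#'
#' Granulocytes turn over fast enough to reach the maximal attainable DNA
#' enrichment; the fitted granulocyte curve's maximum over the observation
#' window, M, is taken as 100% label incorporation and every enrichment value
#' of the series is divided by it.
#'
#' @param gran_fit A fit from [fit_body_water_and_granulocytes], or a single
#'   number M (the scaling maximum) directly.
#' @param series An unscaled [enrichment_series].
#' @return The scaled series; the scaling factor is attached as attribute
#'   `scale_M`.
#' @export
granulocyte_scale <- function(gran_fit, series) {
  stopifnot(inherits(series, "enrichment_series"))
  if (series$scaled) stop("series is already scaled")
  M <- if (is.numeric(gran_fit) && length(gran_fit) == 1) {
    gran_fit
  } else if (inherits(gran_fit, "lk_fit") && gran_fit$type == "bodywater") {
    gran_fit$params$M
  } else {
    stop("gran_fit must be a body-water/granulocyte fit or a numeric maximum")
  }
  if (!is.finite(M) || M <= 0) stop("invalid granulocyte fit: maximum <= 0")
  out <- enrichment_series(series$individual, series$compartment,
                           series$times, series$values / M, scaled = TRUE)
  attr(out, "scale_M") <- M
  out
}

#' Calibrate a measured isotope ratio against enrichment standards
#'
#' Standard solutions of known tracer-to-tracee ratio bracket the measured
#' range; the zero standard provides the natural-abundance baseline, and a
#' straight line fitted to log10(measured - baseline) versus log10(known)
#' over the nonzero standards is inverted for each sample. Monotone in the
#' input; samples at or below baseline return 0 and are flagged.
#'
#' @param standards Data frame with columns `known_ttr` and `measured_ttr`,
#'   including a `known_ttr == 0` row (baseline) and at least three nonzero
#'   standards.
#' @param measured Measured ratio(s) to correct; vectorized.
#' @return Corrected ratio(s); attribute `below_baseline` flags samples that
#'   fell at or below the baseline (returned as 0, with a warning).
#' @export
calibrate_isotope_ratio <- function(standards, measured) {
  stopifnot(is.data.frame(standards),
            all(c("known_ttr", "measured_ttr") %in% names(standards)))
  zero <- standards$known_ttr == 0
  if (!any(zero)) stop("standards must include the zero (baseline) standard")
  baseline <- mean(standards$measured_ttr[zero])
  nz <- standards[!zero, , drop = FALSE]
  if (nrow(nz) < 2) stop("need at least 2 nonzero standards")
  y <- nz$measured_ttr - baseline
  if (any(y <= 0)) stop("nonzero standards must measure above baseline")
  fit <- stats::lm(log10(y) ~ log10(known_ttr), data = nz)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  if (b <= 0) stop("calibration line must be increasing")
  net <- measured - baseline
  below <- net <= 0
  out <- numeric(length(measured))
  out[!below] <- 10^((log10(net[!below]) - a) / b)
  if (any(below)) {
    warning(sum(below), " sample(s) at or below baseline; returned as 0")
  }
  attr(out, "below_baseline") <- below
  out
}

#' Tracer-to-tracee ratios of the calibration standards
#'
#' Known ([M+1]/[M+0]) ratios of the standard solutions used to calibrate
#' DNA enrichment measurements; the zero standard supplies the baseline.
#'
#' @format Numeric vector of length 8.
#' @export
lk_isotope_standards <- c(0, 0.0016, 0.0032, 0.0065, 0.0131, 0.0265,
                          0.0543, 0.1140)
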