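# Leukocyte trend regression, subset-count normalization, the exponential
# cell-number model and loss-rate bookkeeping.

#' Leukocyte counts and subset fractions over time
#'
#' Longitudinal blood counts for one individual: total leukocytes per ml and
#' per-subset fractions of leukocytes. Fractions may sum to more than 1
#' across subsets (subsets overlap across staining panels); no cross-subset
#' constraint is applied. If `fractions` is omitted but `subset_counts`
#' (absolute cells per ml) are given, fractions are derived as
#' subset count / measured leukocytes at the same draw.
#'
#' @param individual Identifier.
#' @param times Days, strictly increasing.
#' @param leukocytes Total leukocytes per ml blood (> 0), one per time.
#' @param fractions Data frame `time_days, subset, fraction` (long format),
#'   fractions in `[0, 1]`; or `NULL`.
#' @param subset_counts Data frame `time_days, subset, count` (cells per
#'   ml); used to derive fractions when `fractions` is `NULL`.
#' @return Object of class `count_series`.
#' @export
count_series <- function(individual, times, leukocytes, fractions = NULL,
                         subset_counts = NULL) {
  if (length(times) != length(leukocytes)) stop("times and leukocytes must match")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(leukocytes <= 0)) stop("leukocytes must be > 0")
  if (is.null(fractions) && !is.null(subset_counts)) {
    stopifnot(all(c("time_days", "subset", "count") %in% names(subset_counts)))
    leuk_at <- stats::approx(times, leukocytes, xout = subset_counts$time_days,
                             rule = 2)$y
    fractions <- data.frame(time_days = subset_counts$time_days,
                            subset = subset_counts$subset,
                            fraction = subset_counts$count / leuk_at)
  }
  if (!is.null(fractions)) {
    stopifnot(all(c("time_days", "subset", "fraction") %in% names(fractions)))
    if (any(fractions$fraction < 0 | fractions$fraction > 1, na.rm = TRUE)) {
      stop("fractions must lie in [0, 1]")
    }
  }
  structure(list(individual = as.character(individual),
                 times = as.numeric(times),
                 leukocytes = as.numeric(leukocytes),
                 fractions = fractions,
                 normalized = NULL),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("Count series: %s, %d draws over %.0f-%.0f d, %d subset(s)%s\n",
              x$individual, length(x$times), min(x$times), max(x$times),
              if (is.null(x$fractions)) 0L else length(unique(x$fractions$subset)),
              if (is.null(x$normalized)) "" else " (normalized)"))
  invisible(x)
}

#' Linear trend through total leukocyte counts
#'
#' Blood leukocyte counts fluctuate (diurnal rhythm, draw-to-draw
#' variation); an ordinary least-squares line through (time, leukocytes)
#' smooths this before subset counts are derived.
#'
#' @param series A [count_series] (>= 3 draws).
#' @return List with `intercept` (cells/ml), `slope` (cells/ml/day) and a
#'   `predict(t)` function.
#' @export
leukocyte_trend <- function(series) {
  stopifnot(inherits(series, "count_series"))
  if (length(series$times) < 3) stop("need >= 3 time points for the trend")
  fit <- stats::lm(leuk ~ t, data = data.frame(t = series$times,
                                               leuk = series$leukocytes))
  cf <- unname(stats::coef(fit))
  list(intercept = cf[1], slope = cf[2],
       predict = function(t) cf[1] + cf[2] * t)
}

#' Normalized subset counts
#'
#' Multiplies the leukocyte trend line by the measured subset fraction at
#' each draw: `normalized_count(subset, t) = trend(t) * fraction(subset, t)`.
#' Draws with a missing fraction are omitted with a warning. Raw leukocyte
#' values are left untouched.
#'
#' @param series A [count_series] with fractions.
#' @param trend Result of [leukocyte_trend] (defaults to fitting it here).
#' @return The series with `normalized`: data frame
#'   `time_days, subset, count`.
#' @export
normalize_counts <- function(series, trend = leukocyte_trend(series)) {
  stopifnot(inherits(series, "count_series"))
  if (is.null(series$fractions)) stop("series has no subset fractions")
  fr <- series$fractions
  miss <- !is.finite(fr$fraction)
  if (any(miss)) {
    warning(sum(miss), " draw(s) with missing fraction omitted")
    fr <- fr[!miss, , drop = FALSE]
  }
  series$normalized <- data.frame(
    time_days = fr$time_days,
    subset = fr$subset,
    count = trend$predict(fr$time_days) * fr$fraction)
  series$trend <- trend[c("intercept", "slope")]
  series
}

#' Production/loss-rate block for one subset
#'
#' Bundles the average per-cell production rate `p` (fixed from the
#' enrichment fit), the fitted net growth rate `r = p - d`, the loss rate
#' `d` and the inclusion-time count `X0`.
#'
#' @param p Average per-cell production rate (per day, >= 0).
#' @param r Net growth rate (per day, signed).
#' @param X0 Cell count at study inclusion (cells per ml, > 0).
#' @return Object of class `loss_rate_block` with fields p, r, d, X0 and a
#'   `clipped` flag when `p - r` fell below 0.
#' @export
loss_rate_block <- function(p, r, X0) {
  stopifnot(p >= 0, X0 > 0)
  d <- loss_rate(p, r)
  structure(list(p = p, r = r, d = as.numeric(d), X0 = X0,
                 clipped = isTRUE(attr(d, "clipped"))),
            class = "loss_rate_block")
}

#' Exponential cell-number model
#'
#' `X(t) = X0 exp((p - d) t)`: cell numbers grow or shrink exponentially at
#' the net rate production minus loss.
#'
#' @param t Days; vectorized.
#' @param block A [loss_rate_block].
#' @return Cells per ml, same length as `t`.
#' @export
exponential_counts <- function(t, block) {
  stopifnot(inherits(block, "loss_rate_block"))
  block$X0 * exp((block$p - block$d) * t)
}

#' Loss rate from production and net growth
#'
#' `d = p - r`, bounded below at 0; a negative difference (net growth faster
#' than production, an estimation artifact) is clipped and flagged.
#'
#' @param p Average per-cell production rate (per day, >= 0).
#' @param r Net growth rate (per day).
#' @return Loss rate (per day) with attribute `clipped`.
#' @export
loss_rate <- function(p, r) {
  stopifnot(all(p >= 0))
  d <- p - r
  clipped <- d < 0
  d[clipped] <- 0
  structure(d, clipped = clipped)
}
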