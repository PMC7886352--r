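# Cohort-level comparison layer: fold changes of group medians, total daily
# production, exact Mann-Whitney and Kruskal-Wallis/Dunn tests.

#' Cohort summary table
#'
#' Long-format table of per-individual summary quantities, one value per
#' (individual, subset, quantity).
#'
#' @param df Data frame with columns `individual`, `group`, `subset`,
#'   `quantity`, `value`. Typical quantities: `production_rate`,
#'   `loss_rate`, `ki67_fraction`, `trec_content`, `count`.
#' @return The validated data frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("individual", "group", "subset", "quantity", "value")
                %in% names(df)))
  key <- paste(df$individual, df$subset, df$quantity)
  if (anyDuplicated(key)) {
    stop("duplicate (individual, subset, quantity) rows")
  }
  structure(as.data.frame(df), class = c("cohort_table", "data.frame"))
}

.cohort_values <- function(table, subset, quantity, group) {
  table$value[table$subset == subset & table$quantity == quantity &
                table$group == group]
}

#' Fold change of group medians
#'
#' median(patients) / median(controls) for one subset and quantity, plus a
#' presentation rounding mirroring how such folds are quoted: halves are
#' kept when they are closer ("3.5 times"), otherwise the nearest integer
#' for folds of 2 or more, one decimal below that.
#'
#' @param table A [cohort_table].
#' @param subset Subset name.
#' @param quantity Quantity name.
#' @param groups Character pair: numerator group, denominator group.
#' @return Fold change (numerator median / denominator median), with the
#'   rounded form as attribute `presentation`.
#' @export
median_fold_change <- function(table, subset, quantity,
                               groups = c("patient", "healthy_control")) {
  stopifnot(inherits(table, "cohort_table"), length(groups) == 2)
  num <- .cohort_values(table, subset, quantity, groups[1])
  den <- .cohort_values(table, subset, quantity, groups[2])
  if (length(num) < 2 || length(den) < 2) stop("need >= 2 values per group")
  m_den <- stats::median(den)
  if (m_den == 0) stop("zero median in denominator group")
  fold <- stats::median(num) / m_den
  half <- round(fold * 2) / 2
  whole <- round(fold)
  pres <- if (fold >= 2) {
    if (abs(fold - half) < abs(fold - whole)) half else whole
  } else {
    round(fold, 1)
  }
  structure(fold, presentation = pres)
}

#' Total daily production of a subset
#'
#' Average per-cell production rate times the median subset cell number:
#' cells produced per day.
#'
#' @param rate Per-cell production rate (per day, >= 0).
#' @param median_count Median cell number (>= 0).
#' @return Cells per day.
#' @export
total_daily_production <- function(rate, median_count) {
  stopifnot(all(rate >= 0), all(median_count >= 0))
  rate * median_count
}

# Exact two-sided Mann-Whitney p-value by enumeration of all rank splits,
# ties handled by midranks. Feasible for n1 + n2 choose n1 up to ~1e5.
.mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(r[splits], nrow = nx))
  mu <- nx * (nx + ny + 1) / 2
  dev <- abs(w_all - mu)
  eps <- 1e-9
  p <- mean(dev >= abs(w_obs - mu) - eps)
  u_obs <- w_obs - nx * (nx + 1) / 2
  list(statistic = u_obs, p.value = min(p, 1))
}

# Normal approximation with tie correction (large groups).
.mw_normal <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  n <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  s2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (s2 == 0) return(list(statistic = u, p.value = 1))
  z <- (u - mu) / sqrt(s2)
  list(statistic = u, p.value = min(1, 2 * stats::pnorm(-abs(z))))
}

# Dunn's pairwise z-tests after Kruskal-Wallis, Bonferroni-adjusted over all
# pairs, with the usual tie correction.
.dunn_test <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(groups)
  pairs <- utils::combn(length(lv), 2)
  res <- data.frame(group1 = lv[pairs[1, ]], group2 = lv[pairs[2, ]],
                    z = NA_real_, p.value = NA_real_)
  n_pairs <- ncol(pairs)
  for (j in seq_len(n_pairs)) {
    g1 <- lv[pairs[1, j]]; g2 <- lv[pairs[2, j]]
    r1 <- r[groups == g1]; r2 <- r[groups == g2]
    se <- sqrt(max(n * (n + 1) / 12 - tie_corr, 0) *
                 (1 / length(r1) + 1 / length(r2)))
    z <- if (se == 0) 0 else (mean(r1) - mean(r2)) / se
    res$z[j] <- z
    res$p.value[j] <- min(1, 2 * stats::pnorm(-abs(z)) * n_pairs)
  }
  res
}

#' Nonparametric group comparison
#'
#' Two groups: two-sided Mann-Whitney test, exact by full enumeration of
#' rank splits (midranks for ties) when both groups have at most 8 values,
#' normal approximation with tie correction otherwise. More than two groups:
#' Kruskal-Wallis, followed by Dunn's pairwise z-tests with Bonferroni
#' adjustment over all pairs. A p-value below 0.05 is the conventional
#' reporting threshold; nothing is filtered here.
#'
#' @param table A [cohort_table].
#' @param subset Subset name.
#' @param quantity Quantity name.
#' @param groups Character vector of two or more group labels.
#' @return List with `method`, `statistic`, `p.value`, and for more than two
#'   groups a `pairwise` data frame of Dunn comparisons.
#' @export
compare_groups <- function(table, subset, quantity,
                           groups = c("patient", "healthy_control")) {
  stopifnot(inherits(table, "cohort_table"), length(groups) >= 2)
  vals <- lapply(groups, function(g) .cohort_values(table, subset, quantity, g))
  if (any(lengths(vals) < 2)) stop("every group needs >= 2 values")
  if (length(groups) == 2) {
    x <- vals[[1]]; y <- vals[[2]]
    if (length(x) <= 8 && length(y) <= 8) {
      res <- .mw_exact(x, y)
      method <- "Mann-Whitney (exact)"
    } else {
      res <- .mw_normal(x, y)
      method <- "Mann-Whitney (normal approximation)"
    }
    list(method = method, statistic = res$statistic, p.value = res$p.value)
  } else {
    values <- unlist(vals)
    glab <- factor(rep(groups, lengths(vals)), levels = groups)
    if (length(unique(values)) == 1) {
      return(list(method = "Kruskal-Wallis + Dunn (Bonferroni)",
                  statistic = 0, p.value = 1,
                  pairwise = .dunn_test(values, glab)))
    }
    kw <- stats::kruskal.test(values, glab)
    list(method = "Kruskal-Wallis + Dunn (Bonferroni)",
         statistic = unname(kw$statistic),
         p.value = kw$p.value,
         pairwise = .dunn_test(values, glab))
  }
}
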