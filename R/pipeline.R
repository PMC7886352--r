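# Pipeline stages (simulate / fit / report) and the command-line entry
# point. All randomness flows from a single seed; every stage writes a JSON
# manifest next to its outputs.

#' Simulate stage: write a synthetic cohort to disk
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed.
#' @param config Optional settings list (see [read_run_config]) or a path
#'   to a YAML file. Defaults to the paper-like preset, 6 patients and 10
#'   controls.
#' @return Invisibly, the list of written paths.
#' @export
lk_simulate <- function(out_dir, seed = 11, config = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- config %||% list()
  n_patients <- config$n_patients %||% 6
  n_controls <- config$n_controls %||% 10
  jitter_sd <- config$jitter_sd %||% 0.15
  subsets <- config$subsets %||% lk_subsets
  p_cfg <- paper_like_config("patient", subsets = subsets)
  c_cfg <- paper_like_config("healthy_control", subsets = subsets)
  if (!is.null(config$noise)) {
    p_cfg$noise <- utils::modifyList(p_cfg$noise, config$noise)
    c_cfg$noise <- utils::modifyList(c_cfg$noise, config$noise)
  }
  cohort <- generate_cohort(n_patients, n_controls, seed = seed,
                            patient_cfg = p_cfg, control_cfg = c_cfg,
                            jitter_sd = jitter_sd)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (nm in c("enrichment", "counts", "qpcr", "trec", "individuals",
               "truth_table")) {
    if (is.null(cohort[[nm]])) next
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(cohort[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  write_manifest(file.path(out_dir, "manifest.json"), "simulate", "ok",
                 outputs = paths, seed = seed,
                 extra = list(n_patients = n_patients,
                              n_controls = n_controls,
                              jitter_sd = jitter_sd, subsets = subsets))
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit stage: body-water/granulocyte and subset fits for a data directory
#'
#' Reads the CSVs written by [lk_simulate] (or equivalently formatted lab
#' exports), and for each individual fits the body-water + granulocyte
#' model, scales the subset enrichment to the granulocyte maximum, derives
#' normalized subset counts from the leukocyte trend, and fits each subset
#' with automatic 1-vs-2 component selection. Optional residual-bootstrap
#' CIs.
#'
#' @param data_dir Directory with `enrichment.csv`, `counts.csv` and
#'   `individuals.csv` (columns `individual`, `group`, `tau`).
#' @param out_dir Output directory.
#' @param seed Seed driving multi-starts and bootstrap.
#' @param n_boot Bootstrap replicates per fit (0 = point estimates only).
#' @param n_starts Multi-start candidates per fit.
#' @return Invisibly, a list with the fit objects (`bodywater`, `subsets`)
#'   and the parameter table.
#' @export
lk_fit_dir <- function(data_dir, out_dir, seed = 1, n_boot = 0,
                       n_starts = 20) {
  enr <- read_enrichment(file.path(data_dir, "enrichment.csv"))
  cnt <- read_counts(file.path(data_dir, "counts.csv"))
  ind <- .read_csv(file.path(data_dir, "individuals.csv"))
  .require_columns(ind, c("individual", "group", "tau"), "individuals table")
  groups <- stats::setNames(ind$group, ind$individual)

  bw_fits <- list(); subset_fits <- list(); log_entries <- list()
  for (i in seq_len(nrow(ind))) {
    id <- ind$individual[i]
    urine <- as_enrichment_series(enr, id, "urine")
    gran <- as_enrichment_series(enr, id, "granulocytes")
    bwfit <- fit_body_water_and_granulocytes(urine, gran, tau = ind$tau[i],
                                             n_starts = n_starts, seed = seed)
    bw_fits[[id]] <- bwfit
    log_entries[[length(log_entries) + 1]] <- list(
      individual = id, stage = "bodywater", n_params = 5L,
      convergence = bwfit$convergence, M = bwfit$params$M)

    cnt_i <- cnt[cnt$individual == id, , drop = FALSE]
    leuk <- unique(cnt_i[, c("time_days", "leukocytes_per_ml")])
    leuk <- leuk[order(leuk$time_days), ]
    cs <- count_series(id, leuk$time_days, leuk$leukocytes_per_ml,
                       subset_counts = data.frame(
                         time_days = cnt_i$time_days, subset = cnt_i$subset,
                         count = cnt_i$subset_count_per_ml))
    cs <- normalize_counts(cs)

    subs <- intersect(lk_subsets, unique(enr$compartment[enr$individual == id]))
    for (nm in subs) {
      series <- granulocyte_scale(bwfit, as_enrichment_series(enr, id, nm))
      ncounts <- cs$normalized[cs$normalized$subset == nm,
                               c("time_days", "count")]
      fit <- fit_subset_auto(series, ncounts, bwfit$params$bw,
                             bwfit$params$c_amp, bwfit$params$M,
                             n_starts = n_starts, seed = seed)
      if (n_boot > 0) fit <- bootstrap_ci(fit, n_boot = n_boot, seed = seed)
      subset_fits[[paste(id, nm, sep = ".")]] <- fit
      log_entries[[length(log_entries) + 1]] <- list(
        individual = id, stage = "subset", subset = nm,
        n_components = fit$n_components,
        selection_p = fit$selection$p_value %||% NA,
        convergence = fit$convergence,
        clipped_fraction = fit$clipped_fraction,
        at_bound = sum(fit$at_bound))
    }
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- fits_to_table(c(bw_fits, subset_fits), groups = groups)
  fit_path <- file.path(out_dir, "fits.csv")
  utils::write.csv(tab, fit_path, row.names = FALSE)
  log_path <- file.path(out_dir, "runlog.json")
  jsonlite::write_json(list(seed = seed, n_boot = n_boot,
                            n_starts = n_starts, fits = log_entries),
                       log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_manifest(file.path(out_dir, "manifest.json"), "fit", "ok",
                 inputs = file.path(data_dir,
                                    c("enrichment.csv", "counts.csv",
                                      "individuals.csv")),
                 outputs = c(fit_path, log_path), seed = seed,
                 extra = list(n_boot = n_boot))
  invisible(list(bodywater = bw_fits, subsets = subset_fits, table = tab))
}

#' Report stage: cohort summaries from a fit table
#'
#' Builds the cohort table (production and loss rates per individual and
#' subset), computes patient-vs-control medians, fold changes and exact
#' Mann-Whitney p-values per subset and quantity, and writes `report.csv`
#' plus a Markdown summary.
#'
#' @param fits_dir Directory containing `fits.csv`.
#' @param out_dir Output directory.
#' @return Invisibly, the report data frame.
#' @export
lk_report <- function(fits_dir, out_dir) {
  tab <- .read_csv(file.path(fits_dir, "fits.csv"))
  .require_columns(tab, c("individual", "group", "subset", "parameter",
                          "estimate"), "fit table")
  sel <- tab$subset != "bodywater" & tab$parameter %in% c("p", "d")
  ct <- cohort_table(data.frame(
    individual = tab$individual[sel], group = tab$group[sel],
    subset = tab$subset[sel],
    quantity = ifelse(tab$parameter[sel] == "p", "production_rate",
                      "loss_rate"),
    value = tab$estimate[sel]))

  rows <- list()
  for (nm in intersect(lk_subsets, unique(ct$subset))) {
    for (q in c("production_rate", "loss_rate")) {
      pat <- .cohort_values(ct, nm, q, "patient")
      con <- .cohort_values(ct, nm, q, "healthy_control")
      if (length(pat) < 2 || length(con) < 2) next
      fold <- tryCatch(median_fold_change(ct, nm, q),
                       error = function(e) NA_real_)
      cmp <- compare_groups(ct, nm, q)
      rows[[length(rows) + 1]] <- data.frame(
        subset = nm, quantity = q,
        median_patient = stats::median(pat),
        median_control = stats::median(con),
        fold_change = as.numeric(fold),
        fold_presentation = if (is.na(fold)) NA_real_ else
          attr(fold, "presentation"),
        test = cmp$method, p_value = cmp$p.value)
    }
  }
  report <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  csv_path <- file.path(out_dir, "report.csv")
  utils::write.csv(report, csv_path, row.names = FALSE)

  md_path <- file.path(out_dir, "report.md")
  lines <- c("# Cohort report", "",
             "Patient vs healthy-control medians per subset.", "",
             "| subset | quantity | median patient | median control | fold | p (MW) |",
             "|---|---|---|---|---|---|")
  for (i in seq_len(nrow(report))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %.4g | %.4g | %.3g | %.3g |",
      report$subset[i], report$quantity[i], report$median_patient[i],
      report$median_control[i], report$fold_change[i], report$p_value[i]))
  }
  writeLines(lines, md_path)
  write_manifest(file.path(out_dir, "manifest.json"), "report", "ok",
                 inputs = file.path(fits_dir, "fits.csv"),
                 outputs = c(csv_path, md_path))
  invisible(report)
}

.parse_flags <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    if (i + 1 > length(args)) stop("flag ", a, " needs a value")
    out[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line pipeline
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--out DIR [--config FILE] [--seed S]`}
#'   \item{fit}{`--data DIR --out DIR [--n-boot N] [--seed S]`}
#'   \item{report}{`--fits DIR --out DIR`}
#'   \item{all}{`--out DIR [--config FILE] [--seed S] [--n-boot N]`; chains
#'     the three stages into `DIR/data`, `DIR/fits`, `DIR/report`.}
#' }
#' All randomness flows from the single `--seed`. Returns (invisibly) exit
#' status 0 on success and 1 with a one-line message otherwise, so it can
#' back an `Rscript` entry point (see `inst/cli/lymphkin.R`).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly.
#' @export
lymphkin_cli <- function(args) {
  status <- tryCatch({
    if (length(args) < 1) stop("usage: lymphkin <simulate|fit|report|all> ...")
    cmd <- args[1]
    flags <- .parse_flags(args[-1])
    seed <- as.integer(flags$seed %||% 1)
    switch(cmd,
      simulate = {
        if (is.null(flags$out)) stop("simulate: --out required")
        lk_simulate(flags$out, seed = seed, config = flags$config)
      },
      fit = {
        if (is.null(flags$data) || is.null(flags$out)) {
          stop("fit: --data and --out required")
        }
        lk_fit_dir(flags$data, flags$out, seed = seed,
                   n_boot = as.integer(flags[["n-boot"]] %||% 0))
      },
      report = {
        if (is.null(flags$fits) || is.null(flags$out)) {
          stop("report: --fits and --out required")
        }
        lk_report(flags$fits, flags$out)
      },
      all = {
        if (is.null(flags$out)) stop("all: --out required")
        lk_simulate(file.path(flags$out, "data"), seed = seed,
                    config = flags$config)
        lk_fit_dir(file.path(flags$out, "data"),
                   file.path(flags$out, "fits"), seed = seed,
                   n_boot = as.integer(flags[["n-boot"]] %||% 0))
        lk_report(file.path(flags$out, "fits"),
                  file.path(flags$out, "report"))
      },
      stop("unknown command: ", cmd))
    0L
  }, error = function(e) {
    message("lymphkin: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
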