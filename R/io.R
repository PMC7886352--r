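# CSV readers/writers with validation, run configuration and manifests.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "))
  }
}

.offending <- function(idx) paste(utils::head(which(idx), 10), collapse = ", ")

#' Read an enrichment table
#'
#' CSV dialect: one row per observation with columns `individual`,
#' `compartment`, `time_days`, `enrichment`, `scaled_flag`. Unknown
#' compartments, negative times or values, and duplicated
#' (individual, compartment, time) rows are rejected with the offending row
#' numbers.
#'
#' @param path CSV file.
#' @return Validated data frame (possibly empty).
#' @export
read_enrichment <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("individual", "compartment", "time_days",
                         "enrichment", "scaled_flag"), "enrichment table")
  if (nrow(df) == 0) return(df)
  bad <- !df$compartment %in% lk_compartments
  if (any(bad)) stop("unknown compartment(s) at row(s): ", .offending(bad))
  if (any(df$time_days < 0)) {
    stop("negative time_days at row(s): ", .offending(df$time_days < 0))
  }
  if (any(df$enrichment < 0)) {
    stop("negative enrichment at row(s): ", .offending(df$enrichment < 0))
  }
  key <- paste(df$individual, df$compartment, df$time_days)
  if (anyDuplicated(key)) {
    stop("duplicated (individual, compartment, time) at row(s): ",
         .offending(duplicated(key)))
  }
  df
}

#' Read a cell-count table
#'
#' CSV dialect: `individual`, `time_days`, `leukocytes_per_ml`, `subset`,
#' and `subset_count_per_ml` and/or `fraction`.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_counts <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("individual", "time_days", "leukocytes_per_ml",
                         "subset"), "count table")
  if (!any(c("subset_count_per_ml", "fraction") %in% names(df))) {
    stop("count table: need subset_count_per_ml or fraction")
  }
  if (nrow(df) == 0) return(df)
  bad <- !df$subset %in% lk_subsets
  if (any(bad)) stop("unknown subset(s) at row(s): ", .offending(bad))
  if (any(df$leukocytes_per_ml <= 0)) {
    stop("non-positive leukocytes at row(s): ",
         .offending(df$leukocytes_per_ml <= 0))
  }
  key <- paste(df$individual, df$subset, df$time_days)
  if (anyDuplicated(key)) {
    stop("duplicated (individual, subset, time) at row(s): ",
         .offending(duplicated(key)))
  }
  df
}

#' Read a KREC qPCR table
#'
#' CSV dialect: `individual`, `subset`, `target` (signal|coding|albumin),
#' `ct_mean`, `control_flag`.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_qpcr <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("individual", "subset", "target", "ct_mean",
                         "control_flag"), "qPCR table")
  if (nrow(df) == 0) return(df)
  bad <- !df$target %in% c("signal", "coding", "albumin")
  if (any(bad)) stop("unknown target(s) at row(s): ", .offending(bad))
  if (any(df$ct_mean <= 0 | df$ct_mean >= 45)) {
    stop("Ct out of (0, 45) at row(s): ",
         .offending(df$ct_mean <= 0 | df$ct_mean >= 45))
  }
  df
}

#' Read a TREC table
#'
#' CSV dialect: `individual`, `subset`, `trec_copies`, `cell_equivalents`.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_trec <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("individual", "subset", "trec_copies",
                         "cell_equivalents"), "TREC table")
  if (nrow(df) > 0 && any(df$cell_equivalents <= 0)) {
    stop("non-positive cell_equivalents at row(s): ",
         .offending(df$cell_equivalents <= 0))
  }
  df
}

#' Build an enrichment series from a table
#'
#' Extracts one individual x compartment from an enrichment table (rows
#' sorted by time).
#'
#' @param df Data frame from [read_enrichment].
#' @param individual,compartment Selection.
#' @return An [enrichment_series].
#' @export
as_enrichment_series <- function(df, individual, compartment) {
  sel <- df[df$individual == individual & df$compartment == compartment, ,
            drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no rows for ", individual, " / ", compartment)
  }
  sel <- sel[order(sel$time_days), , drop = FALSE]
  enrichment_series(individual, compartment, sel$time_days, sel$enrichment,
                    scaled = isTRUE(all(sel$scaled_flag)))
}

#' Serialize fits to a parameter table
#'
#' One row per parameter: `individual`, `group`, `subset`, `n_components`,
#' `parameter`, `estimate`, `ci_low`, `ci_high` (CIs `NA` without
#' bootstrap).
#'
#' @param fits List of `lk_fit` objects.
#' @param groups Named character vector mapping individual to group.
#' @return Data frame.
#' @export
fits_to_table <- function(fits, groups = NULL) {
  rows <- lapply(fits, function(fit) {
    est <- fit$estimates
    lo <- hi <- rep(NA_real_, length(est))
    if (!is.null(fit$ci95)) {
      idx <- match(names(est), rownames(fit$ci95))
      lo <- fit$ci95[idx, 1]; hi <- fit$ci95[idx, 2]
    }
    data.frame(
      individual = fit$individual,
      group = if (is.null(groups)) NA_character_ else
        unname(groups[fit$individual]),
      subset = if (fit$type == "subset") fit$subset else "bodywater",
      n_components = fit$n_components,
      parameter = names(est), estimate = unname(est),
      ci_low = unname(lo), ci_high = unname(hi))
  })
  do.call(rbind, rows)
}

#' Write a run manifest
#'
#' JSON manifest listing inputs, outputs, seed, package version and
#' per-stage status; written even when a stage partially fails.
#'
#' @param path Output JSON path.
#' @param stage Stage name.
#' @param status `"ok"` or an error summary.
#' @param inputs,outputs Character vectors of paths.
#' @param seed Seed used.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, stage, status, inputs = character(),
                           outputs = character(), seed = NA, extra = list()) {
  manifest <- c(list(
    stage = stage, status = status,
    package = "lymphkin",
    version = as.character(utils::packageVersion("lymphkin")),
    seed = seed, inputs = inputs, outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Read a run configuration
#'
#' YAML key-value tree controlling the simulate stage; recognized keys:
#' `n_patients`, `n_controls`, `jitter_sd`, `subsets`, and a `noise` block
#' (`sd_enrichment`, `sd_counts`, `sd_ct`). Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("n_patients", "n_controls", "jitter_sd", "subsets", "noise")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$subsets)) {
    bad <- setdiff(cfg$subsets, lk_subsets)
    if (length(bad)) stop("unknown subset(s) in config: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(cfg$noise)) {
    bad <- setdiff(names(cfg$noise), c("sd_enrichment", "sd_counts", "sd_ct"))
    if (length(bad)) stop("unknown noise key(s): ", paste(bad, collapse = ", "))
  }
  cfg
}
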