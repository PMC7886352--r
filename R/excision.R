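# Excision-circle arithmetic: B-cell replication history and coding-joint
# frequency from KREC qPCR, TREC content per cell.

#' A qPCR measurement triple
#'
#' Mean cycle-threshold values (each the mean of two technical replicates)
#' for the KREC signal joint, the intronRSS-Kde coding joint and the albumin
#' control gene of one DNA sample.
#'
#' @param ct_signal_joint,ct_coding_joint,ct_albumin Ct values in (0, 45);
#'   any may be `NA` if that target was not run.
#' @param is_control_line Whether this is the U698-DB01 reference line.
#' @return Object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_signal_joint = NA_real_,
                             ct_coding_joint = NA_real_,
                             ct_albumin = NA_real_,
                             is_control_line = FALSE) {
  for (ct in c(ct_signal_joint, ct_coding_joint, ct_albumin)) {
    if (!is.na(ct) && (ct <= 0 || ct >= 45)) stop("Ct values must lie in (0, 45)")
  }
  structure(list(ct_signal_joint = ct_signal_joint,
                 ct_coding_joint = ct_coding_joint,
                 ct_albumin = ct_albumin,
                 is_control_line = isTRUE(is_control_line)),
            class = "qpcr_measurement")
}

#' B-cell replication history from KREC Ct values
#'
#' Every division doubles the coding joints while the episomal signal-joint
#' KRECs are not replicated, so the signal-minus-coding Ct difference grows
#' by one cycle per division. Subtracting the same difference measured in
#' the undivided U698-DB01 control line corrects for assay efficiency:
#' `(Ct_sj - Ct_cj)_sample - (Ct_sj - Ct_cj)_control` estimates the number
#' of cell divisions since the rearrangement.
#'
#' @param sample,control [qpcr_measurement] objects; `control` is the
#'   U698-DB01 reference.
#' @return Number of divisions (may be negative through assay noise; flagged
#'   via attribute `negative`).
#' @export
replication_history <- function(sample, control) {
  stopifnot(inherits(sample, "qpcr_measurement"),
            inherits(control, "qpcr_measurement"))
  cts <- c(sample$ct_signal_joint, sample$ct_coding_joint,
           control$ct_signal_joint, control$ct_coding_joint)
  if (anyNA(cts)) stop("signal and coding Ct required in sample and control")
  d <- (sample$ct_signal_joint - sample$ct_coding_joint) -
    (control$ct_signal_joint - control$ct_coding_joint)
  structure(d, negative = d < 0)
}

#' Fraction of cells carrying a coding joint
#'
#' `2^((Ct_alb - Ct_cj)_sample - (Ct_alb - Ct_cj)_control) x 100%`: the
#' albumin-referenced coding-joint abundance relative to the U698-DB01 line,
#' in percent. Values above 100% (assay noise) are flagged, not clipped.
#'
#' @param sample,control [qpcr_measurement] objects.
#' @return Percentage, attribute `above_100` flags implausible values.
#' @export
coding_joint_fraction <- function(sample, control) {
  stopifnot(inherits(sample, "qpcr_measurement"),
            inherits(control, "qpcr_measurement"))
  cts <- c(sample$ct_albumin, sample$ct_coding_joint,
           control$ct_albumin, control$ct_coding_joint)
  if (anyNA(cts)) stop("albumin and coding Ct required in sample and control")
  pct <- 2^((sample$ct_albumin - sample$ct_coding_joint) -
              (control$ct_albumin - control$ct_coding_joint)) * 100
  structure(pct, above_100 = pct > 100)
}

#' TREC content per cell
#'
#' Signal-joint TREC copies divided by the number of cell equivalents in
#' the DNA input.
#'
#' @param trec_copies TREC copy number (>= 0).
#' @param cell_equivalents Cell equivalents of input DNA (> 0); see
#'   [cells_from_dna].
#' @return TRECs per cell; values of 1 or more (at most one TREC per cell is
#'   plausible) are flagged via attribute `implausible`.
#' @export
trec_content <- function(trec_copies, cell_equivalents) {
  stopifnot(all(trec_copies >= 0))
  if (any(cell_equivalents <= 0)) stop("cell_equivalents must be > 0")
  x <- trec_copies / cell_equivalents
  structure(x, implausible = x >= 1)
}

#' Cell equivalents of a genomic DNA input
#'
#' Converts nanograms of genomic DNA to diploid cell equivalents assuming
#' 6.6 pg per diploid genome (configurable).
#'
#' @param dna_ng DNA input in nanograms.
#' @param pg_per_cell Genomic DNA mass per diploid cell in picograms.
#' @return Cell equivalents.
#' @export
cells_from_dna <- function(dna_ng, pg_per_cell = 6.6) {
  stopifnot(pg_per_cell > 0, all(dna_ng >= 0))
  dna_ng * 1000 / pg_per_cell
}
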