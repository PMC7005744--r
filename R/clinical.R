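#' Classify tumor/normal pairs by regulator expression and inclusion change
#'
#' Applies the closed-form grouping rules used for matched tumor /
#' non-tumor (NT) pairs: a pair is \code{ADAR12_high} when ADAR1 or ADAR2
#' expression in the tumor is at least \code{fold_threshold} times the NT
#' level (boundary included), \code{ADAR2_high} when ADAR2 alone clears the
#' threshold; exon inclusion is \code{up} when tumor PSI exceeds NT PSI by
#' strictly more than \code{psi_threshold} (5 percentage points by default),
#' \code{down} when it falls short by strictly more, and \code{no_change}
#' otherwise. Rows with missing fields are skipped with a warning.
#'
#' @param pairs data.frame with columns \code{patient_id}, \code{adar1_fold},
#'   \code{adar2_fold} (tumor/NT expression ratios, > 0), \code{psi_tumor},
#'   \code{psi_nt} (fractions in [0, 1]).
#' @param fold_threshold Expression fold threshold (default 1.5, inclusive).
#' @param psi_threshold Inclusion-change threshold on the PSI fraction
#'   (default 0.05, strict).
#' @return The input with added columns \code{adar12_group}
#'   (\code{ADAR12_high} / \code{ADAR12_normal_low}), \code{adar2_group}
#'   (\code{ADAR2_high} / \code{ADAR2_normal_low}) and \code{inclusion_group}
#'   (\code{up} / \code{down} / \code{no_change}).
#' @export
classify_pairs <- function(pairs, fold_threshold = 1.5, psi_threshold = 0.05) {
  need <- c("patient_id", "adar1_fold", "adar2_fold", "psi_tumor", "psi_nt")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) stop("missing columns: ",
                                 paste(missing_cols, collapse = ", "))
  ok <- stats::complete.cases(pairs[need])
  if (any(!ok)) {
    warning("skipping ", sum(!ok), " record(s) with missing fields")
    pairs <- pairs[ok, , drop = FALSE]
  }
  stopifnot(all(pairs$adar1_fold > 0), all(pairs$adar2_fold > 0),
            all(pairs$psi_tumor >= 0 & pairs$psi_tumor <= 1),
            all(pairs$psi_nt >= 0 & pairs$psi_nt <= 1))
  dpsi <- pairs$psi_tumor - pairs$psi_nt
  pairs$adar12_group <- ifelse(pairs$adar1_fold >= fold_threshold |
                                 pairs$adar2_fold >= fold_threshold,
                               "ADAR12_high", "ADAR12_normal_low")
  pairs$adar2_group <- ifelse(pairs$adar2_fold >= fold_threshold,
                              "ADAR2_high", "ADAR2_normal_low")
  # strict > with a 1e-9 guard so differences like 0.55 - 0.50 sit exactly
  # on the printed boundary rather than a representation error above it
  pairs$inclusion_group <- ifelse(dpsi > psi_threshold + 1e-9, "up",
                                  ifelse(dpsi < -psi_threshold - 1e-9, "down",
                                         "no_change"))
  pairs
}

#' RIP enrichment as percent of input
#'
#' \deqn{\%Input = 2^{-\Delta Ct} \times 100, \quad
#'       \Delta Ct = Ct_{RIP} - (Ct_{input} - dilution~factor)}
#' The dilution factor is in Ct units (log2 of the input dilution; e.g.
#' a 1\% input carries \code{log2(100) = 6.644}).
#'
#' @param ct_rip,ct_input qPCR cycle thresholds.
#' @param dilution_factor Input dilution correction in cycles.
#' @return Percent of input (100 means all of the input).
#' @export
rip_percent_input <- function(ct_rip, ct_input, dilution_factor) {
  stopifnot(is.finite(ct_rip), is.finite(ct_input), is.finite(dilution_factor))
  dct <- ct_rip - (ct_input - dilution_factor)
  2^(-dct) * 100
}

#' Xenograft tumor volume
#'
#' Ellipsoid approximation \eqn{V = 0.5 \times L \times W^2} with the
#' convention that length is the longer axis; inputs violating it are swapped
#' with a warning.
#'
#' @param length,width Caliper measurements in mm.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length, width) {
  stopifnot(all(length >= 0), all(width >= 0))
  swap <- width > length
  if (any(swap)) {
    warning("width > length for ", sum(swap), " measurement(s); swapping")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  0.5 * length * width^2
}
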