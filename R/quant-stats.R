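# Intensity-weighted peptide-level summary statistics: weighted mean length
# and net charge, relative molar amino-acid abundance, and length
# distributions per sample/fraction.

#' Additive per-residue charge model
#'
#' Net peptide charge at neutral pH approximated by summing fixed
#' per-residue contributions: Asp and Glu contribute -1, Arg and Lys +1, and
#' His +0.1; all other residues and the termini contribute 0.
#'
#' @param contributions named numeric vector of per-residue contributions;
#'   names must be canonical one-letter codes. Unnamed residues default to 0.
#' @return Named numeric vector of length 20 (class `charge_model`).
#' @export
charge_model <- function(contributions = c(D = -1, E = -1, R = 1, K = 1,
                                           H = 0.1)) {
  if (length(contributions) &&
      !all(names(contributions) %in% AA_LETTERS)) {
    stop("charge model keys must be canonical amino-acid letters")
  }
  full <- stats::setNames(numeric(20L), AA_LETTERS)
  full[names(contributions)] <- contributions
  structure(full, class = "charge_model")
}

#' Intensity-weighted relative peptide abundance
#'
#' Normalizes a sample's peptide intensities to weights summing to 1;
#' zero-intensity (identified but unquantified) peptides receive weight 0.
#'
#' @param intensities non-negative numeric vector.
#' @return Numeric weight vector, `sum(w) == 1`.
#' @export
relative_abundance <- function(intensities) {
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  intensities[is.na(intensities)] <- 0
  total <- sum(intensities)
  if (total <= 0) stop("no quantified peptides in sample")
  intensities / total
}

#' Net peptide charge under an additive residue model
#'
#' @param sequence character vector of canonical AA sequences.
#' @param model a [charge_model()].
#' @return Numeric vector of net charges (termini ignored).
#' @export
peptide_charge <- function(sequence, model = charge_model()) {
  counts <- aa_count_matrix(sequence)
  drop(counts %*% unclass(model)[colnames(counts)])
}

#' Weighted mean
#'
#' @param values numeric vector.
#' @param weights weight vector of the same length, summing to 1 (as
#'   produced by [relative_abundance()]).
#' @return `sum(weights * values)`.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  sum(weights * values)
}

#' Relative molar amino-acid abundance
#'
#' Intensity-weighted residue-pool composition of a sample:
#' `p_aa = sum_i w_i n_ia / sum_i w_i L_i`, where `w_i` is peptide i's
#' relative abundance, `n_ia` its count of residue `aa`, and `L_i` its
#' length. The residue-pool denominator makes the charge-linearity identity
#' (weighted mean charge = weighted mean length x per-residue net charge)
#' hold exactly.
#'
#' @param table a [peptide_table()].
#' @param sample sample id.
#' @return Named numeric vector over the 20 canonical AAs, summing to 1.
#' @export
aa_molar_abundance <- function(table, sample) {
  stopifnot(inherits(table, "peptide_table"))
  if (!sample %in% table$samples) stop(sprintf("unknown sample '%s'", sample))
  w <- relative_abundance(table$intensity[, sample])
  counts <- aa_count_matrix(table$sequence)
  pool <- drop(w %*% counts)
  pool / sum(pool)
}

default_length_bins <- function() {
  list("3-5" = c(3L, 5L), "6-10" = c(6L, 10L),
       "11-20" = c(11L, 20L), "21-65" = c(21L, 65L))
}

#' Summarize a fraction (sample) of a peptide table
#'
#' Computes the per-fraction summary block: identification count, arithmetic
#' and intensity-weighted mean peptide length and net charge, relative molar
#' AA abundance, and an intensity-weighted length histogram. Arithmetic
#' means run over all retained identifications; weighted means run over
#' quantified peptides only (zero intensity = weight 0).
#'
#' @param table a filtered [peptide_table()].
#' @param sample sample id.
#' @param model a [charge_model()].
#' @param bins named list of `c(lo, hi)` length bins (inclusive) for the
#'   intensity-weighted length histogram.
#' @return Object of class `fraction_summary`.
#' @export
summarize_fraction <- function(table, sample, model = charge_model(),
                               bins = default_length_bins()) {
  stopifnot(inherits(table, "peptide_table"))
  if (!sample %in% table$samples) stop(sprintf("unknown sample '%s'", sample))
  len <- nchar(table$sequence)
  charge <- peptide_charge(table$sequence, model)
  w <- relative_abundance(table$intensity[, sample])
  quant <- w > 0
  hist <- vapply(bins, function(b) {
    sum(w[len >= b[1] & len <= b[2]])
  }, numeric(1))
  hist_total <- sum(hist)
  if (hist_total > 0) hist <- hist / hist_total
  structure(list(
    sample_id = sample,
    n_peptide_ids = length(len),
    mean_length = mean(len),
    weighted_mean_length = weighted_mean(len, w),
    mean_charge = mean(charge),
    weighted_mean_charge = weighted_mean(charge, w),
    aa_abundance = aa_molar_abundance(table, sample),
    length_histogram = hist,
    n_quantified = sum(quant)
  ), class = "fraction_summary")
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat(sprintf("<fraction_summary> %s: %d IDs (%d quantified)\n",
              x$sample_id, x$n_peptide_ids, x$n_quantified))
  cat(sprintf("  length: mean %.2f, weighted mean %.2f\n",
              x$mean_length, x$weighted_mean_length))
  cat(sprintf("  charge: mean %.2f, weighted mean %.2f\n",
              x$mean_charge, x$weighted_mean_charge))
  invisible(x)
}

#' Summary table across fractions
#'
#' Stacks [summarize_fraction()] results into the standard report layout:
#' one row per statistic (IDs, mean/weighted length and charge, then the 20
#' AA abundances), one column per sample.
#'
#' @param table a [peptide_table()].
#' @param samples sample ids (default: all).
#' @inheritParams summarize_fraction
#' @return A data.frame with a `statistic` column plus one column per sample.
#' @export
summary_table <- function(table, samples = table$samples,
                          model = charge_model(),
                          bins = default_length_bins()) {
  cols <- lapply(samples, function(s) {
    fs <- summarize_fraction(table, s, model, bins)
    c(peptide_ids = fs$n_peptide_ids,
      mean_length = fs$mean_length,
      weighted_mean_length = fs$weighted_mean_length,
      mean_charge = fs$mean_charge,
      weighted_mean_charge = fs$weighted_mean_charge,
      fs$aa_abundance)
  })
  out <- data.frame(statistic = names(cols[[1]]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(samples)) out[[samples[i]]] <- unname(cols[[i]])
  out
}
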