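# Antioxidant score handling: attach externally predicted free
# radical-scavenging (FRS) and metal-chelating (CHE) scores to peptides,
# aggregate against activity thresholds, compare score distributions, and
# decompose cross-fraction peptide overlap.

#' Construct a score table
#'
#' Per-peptide antioxidant propensity scores in [0, 1], as produced by an
#' external sequence-based predictor. Scores are defined only for peptides
#' within the predictor's scorable length range (default 3-30 residues).
#'
#' @param sequence character vector of peptide sequences.
#' @param frs,che numeric scores in `[0, 1]`.
#' @param scorable_range length range `(min, max)` the predictor accepts.
#' @return A data.frame of class `score_table` with columns `sequence`,
#'   `frs`, `che`.
#' @export
score_table <- function(sequence, frs, che, scorable_range = c(3L, 30L)) {
  sequence <- toupper(as.character(sequence))
  stop_noncanonical(sequence, "scored sequence")
  stopifnot(length(frs) == length(sequence),
            length(che) == length(sequence))
  if (any(frs < 0 | frs > 1 | che < 0 | che > 1, na.rm = TRUE)) {
    stop("scores must lie in [0, 1]")
  }
  len <- nchar(sequence)
  if (any(len < scorable_range[1] | len > scorable_range[2])) {
    stop(sprintf("scored sequences must be %d-%d residues",
                 scorable_range[1], scorable_range[2]))
  }
  if (anyDuplicated(sequence)) stop("duplicate sequences in score table")
  structure(
    data.frame(sequence = sequence, frs = as.numeric(frs),
               che = as.numeric(che), stringsAsFactors = FALSE),
    class = c("score_table", "data.frame"),
    scorable_range = scorable_range
  )
}

#' Read a score table TSV (columns: sequence, FRS, CHE)
#'
#' @param path TSV path; column names matched case-insensitively.
#' @inheritParams score_table
#' @export
read_score_table <- function(path, scorable_range = c(3L, 30L)) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("sequence", "frs", "che")) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: missing column '%s'", col))
    }
  }
  score_table(df$sequence, df$frs, df$che, scorable_range)
}

#' Write a score table TSV
#' @param scores a [score_table()].
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  out <- data.frame(sequence = scores$sequence, FRS = scores$frs,
                    CHE = scores$che)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Activity-score thresholds
#'
#' Defaults are the predictor's published operating points: a peptide is
#' called active when FRS >= 0.43 or CHE >= 0.30 (inclusive comparison).
#'
#' @param frs_threshold,che_threshold numeric in `[0, 1]`.
#' @export
threshold_config <- function(frs_threshold = 0.43, che_threshold = 0.30) {
  stopifnot(frs_threshold >= 0, frs_threshold <= 1,
            che_threshold >= 0, che_threshold <= 1)
  structure(list(frs_threshold = frs_threshold,
                 che_threshold = che_threshold),
            class = "threshold_config")
}

#' Attach scores to a peptide table
#'
#' Peptides inside the scorable length range with a score-table entry get
#' `frs`/`che` values; all others are marked unscored (`NA`) and excluded
#' from score statistics. A coverage report (scored counts and the unscored
#' intensity share per sample) is attached as attribute `"score_coverage"`.
#'
#' @param table a [peptide_table()].
#' @param scores a [score_table()].
#' @return The table with `$frs` and `$che` vectors added.
#' @export
attach_scores <- function(table, scores) {
  stopifnot(inherits(table, "peptide_table"),
            inherits(scores, "score_table"))
  rng <- attr(scores, "scorable_range")
  len <- nchar(table$sequence)
  idx <- match(table$sequence, scores$sequence)
  idx[len < rng[1] | len > rng[2]] <- NA
  table$frs <- scores$frs[idx]
  table$che <- scores$che[idx]
  scored <- !is.na(idx)
  unscored_share <- vapply(table$samples, function(s) {
    tot <- sum(table$intensity[, s])
    if (tot <= 0) return(NA_real_)
    sum(table$intensity[!scored, s]) / tot
  }, numeric(1))
  attr(table, "score_coverage") <- list(
    n_peptides = length(len),
    n_scored = sum(scored),
    coverage = if (length(len)) sum(scored) / length(len) else NA_real_,
    unscored_intensity_share = unscored_share
  )
  table
}

#' Aggregate antioxidant scores for one sample
#'
#' Computes threshold-based qualitative and quantitative metrics for a
#' scored sample: the count and fraction of scored peptide IDs at or above
#' the threshold, and the intensity-weighted abundance share of
#' above-threshold peptides. Two intensity shares are reported:
#' `intensity_frac_above` with weights renormalized over scored+quantified
#' peptides, and `intensity_frac_above_raw` with the denominator taken over
#' all quantified peptides (the share of total peptide-level intensity).
#'
#' @param table a scored table from [attach_scores()].
#' @param sample sample id.
#' @param property `"FRS"` or `"CHE"`.
#' @param config a [threshold_config()].
#' @return Object of class `aggregation_result`.
#' @export
aggregate_scores <- function(table, sample, property = c("FRS", "CHE"),
                             config = threshold_config()) {
  property <- match.arg(property)
  stopifnot(inherits(table, "peptide_table"))
  if (is.null(table$frs)) stop("table has no scores; call attach_scores()")
  if (!sample %in% table$samples) stop(sprintf("unknown sample '%s'", sample))
  score <- if (property == "FRS") table$frs else table$che
  threshold <- if (property == "FRS") config$frs_threshold else
    config$che_threshold
  scored <- !is.na(score)
  if (!any(scored)) stop("no scored peptides in table")
  intensity <- table$intensity[, sample]
  w_all <- relative_abundance(intensity)
  sq <- scored & intensity > 0
  if (!any(sq)) stop(sprintf("no scored, quantified peptides in '%s'", sample))
  w_sq <- intensity[sq] / sum(intensity[sq])
  above_sq <- score[sq] >= threshold
  above_scored <- score[scored] >= threshold
  q <- stats::quantile(score[scored], c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(
    sample_id = sample,
    property = property,
    threshold = threshold,
    n_scored = sum(scored),
    n_above = sum(above_scored),
    frac_ids_above = mean(above_scored),
    intensity_frac_above = sum(w_sq[above_sq]),
    intensity_frac_above_raw = sum(w_all[sq][above_sq]),
    mean_score = mean(score[scored]),
    quartiles = c(q1 = q[1], median = q[2], q3 = q[3])
  ), class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf(
    "<aggregation_result> %s %s>=%.2f: %d/%d IDs (%.1f%%), %.1f%% of intensity\n",
    x$sample_id, x$property, x$threshold, x$n_above, x$n_scored,
    100 * x$frac_ids_above, 100 * x$intensity_frac_above_raw))
  invisible(x)
}

#' Compare score distributions across groups
#'
#' One-way ANOVA with Tukey HSD post-hoc pairwise comparisons (equal
#' variances assumed; studentized-range adjustment). Statistical plumbing
#' for comparing per-fraction score distributions.
#'
#' @param groups named list of numeric score vectors (>= 2 groups, each with
#'   >= 2 values).
#' @return List with `f_statistic`, `p_value`, and a `tukey` data.frame of
#'   pairwise differences and adjusted p values.
#' @export
compare_score_means <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(
    f_statistic = an[["F value"]][1],
    p_value = an[["Pr(>F)"]][1],
    tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                       p_adj = tk[, "p adj"], row.names = NULL)
  )
}

#' Exclusive overlap decomposition of peptide sets
#'
#' UpSet-style decomposition: every peptide in the union is assigned to
#' exactly one membership pattern, so the `2^k - 1` exclusive intersection
#' sizes sum to the union size.
#'
#' @param sets named list (>= 2) of character vectors of peptide sequences.
#' @return List with `patterns` (data.frame: one logical column per set,
#'   plus `count`), `conserved` (in all sets), `unique_counts` and
#'   `unique_shares` (per set, share of that set's peptides).
#' @export
overlap_analysis <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, nrow = length(universe),
                   dimnames = list(NULL, names(sets)))
  key <- apply(member * 1L, 1, paste, collapse = "")
  tab <- table(key)
  pat <- do.call(rbind, lapply(names(tab), function(k) {
    as.logical(as.integer(strsplit(k, "")[[1]]))
  }))
  patterns <- as.data.frame(pat)
  names(patterns) <- names(sets)
  patterns$count <- as.integer(tab)
  only_one <- rowSums(member) == 1
  unique_counts <- vapply(seq_along(sets), function(j) {
    sum(member[, j] & only_one)
  }, integer(1))
  names(unique_counts) <- names(sets)
  structure(list(
    patterns = patterns[order(-patterns$count), , drop = FALSE],
    n_union = length(universe),
    conserved = sum(rowSums(member) == ncol(member)),
    unique_counts = unique_counts,
    unique_shares = unique_counts / vapply(sets, length, integer(1))
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d peptides in union; %d conserved in all\n",
              x$n_union, x$conserved))
  invisible(x)
}

#' Collapse duplicate sequences in a peptide table
#'
#' Sums intensities over rows sharing a sequence (e.g. charge states) so
#' set-level analyses operate on unique sequences.
#'
#' @param table a [peptide_table()].
#' @return A [peptide_table()] with unique sequences.
#' @export
collapse_sequences <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  if (!anyDuplicated(table$sequence)) return(table)
  f <- factor(table$sequence, levels = unique(table$sequence))
  intensity <- apply(table$intensity, 2, function(col) {
    as.vector(tapply(col, f, sum))
  })
  intensity <- matrix(intensity, ncol = length(table$samples),
                      dimnames = list(NULL, table$samples))
  first <- !duplicated(table$sequence)
  peptide_table(
    sequence = levels(f),
    intensity = intensity,
    proteins = table$proteins[first],
    is_reverse = table$is_reverse[first],
    is_contaminant = table$is_contaminant[first]
  )
}
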