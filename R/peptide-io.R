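# Peptide identification tables: canonical in-memory model, MaxQuant-style
# TSV reading/writing, and the standard post-search filter.

#' Construct a peptide table
#'
#' The canonical container for filtered peptide identifications: one row per
#' peptide, with decoy/contaminant flags and a per-sample intensity matrix in
#' arbitrary MS intensity units.
#'
#' @param sequence character vector of uppercase canonical AA sequences.
#' @param intensity numeric matrix (rows = peptides, named columns = samples)
#'   of non-negative intensities, or a named numeric vector for a single
#'   sample.
#' @param proteins character vector of protein accessions per peptide
#'   (semicolon-separated for shared peptides). Defaults to `""`.
#' @param is_reverse,is_contaminant logical flags per peptide.
#' @return An object of class `peptide_table`: a list with elements
#'   `sequence`, `proteins`, `is_reverse`, `is_contaminant`, `intensity`
#'   (matrix) and `samples` (ordered sample ids).
#' @export
peptide_table <- function(sequence, intensity,
                          proteins = rep("", length(sequence)),
                          is_reverse = rep(FALSE, length(sequence)),
                          is_contaminant = rep(FALSE, length(sequence))) {
  sequence <- toupper(as.character(sequence))
  stop_noncanonical(sequence, "peptide sequence")
  if (is.vector(intensity)) {
    intensity <- matrix(intensity, ncol = 1,
                        dimnames = list(NULL, "sample_1"))
  }
  intensity <- as.matrix(intensity)
  if (is.null(colnames(intensity))) {
    stop("intensity matrix must have sample ids as column names")
  }
  if (anyDuplicated(colnames(intensity))) {
    stop("sample ids must be unique")
  }
  if (nrow(intensity) != length(sequence)) {
    stop("intensity must have one row per peptide")
  }
  storage.mode(intensity) <- "double"
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  intensity[is.na(intensity)] <- 0
  stopifnot(length(proteins) == length(sequence),
            length(is_reverse) == length(sequence),
            length(is_contaminant) == length(sequence))
  structure(
    list(sequence = sequence,
         proteins = as.character(proteins),
         is_reverse = as.logical(is_reverse),
         is_contaminant = as.logical(is_contaminant),
         intensity = intensity,
         samples = colnames(intensity)),
    class = "peptide_table"
  )
}

#' @export
print.peptide_table <- function(x, ...) {
  cat(sprintf("<peptide_table> %d peptides x %d samples (%s)\n",
              length(x$sequence), length(x$samples),
              paste(utils::head(x$samples, 6), collapse = ", ")))
  rep_n <- sum(x$is_reverse)
  con_n <- sum(x$is_contaminant)
  if (rep_n + con_n > 0) {
    cat(sprintf("  flags: %d reverse, %d contaminant\n", rep_n, con_n))
  }
  rpt <- attr(x, "filter_report")
  if (!is.null(rpt)) {
    cat(sprintf("  filtered: %d in -> %d retained\n", rpt$input, rpt$retained))
  }
  invisible(x)
}

#' @export
length.peptide_table <- function(x) length(x$sequence)

subset_peptide_table <- function(table, idx) {
  out <- peptide_table(
    sequence = table$sequence[idx],
    intensity = table$intensity[idx, , drop = FALSE],
    proteins = table$proteins[idx],
    is_reverse = table$is_reverse[idx],
    is_contaminant = table$is_contaminant[idx]
  )
  out
}

#' MaxQuant peptides.txt column dialect
#'
#' Maps logical roles to column names in a tab-separated peptide
#' identification table. Defaults follow MaxQuant's `peptides.txt`: flag
#' columns use a `"+"` marker and per-sample intensities live in columns
#' named `Intensity <sample>`.
#'
#' @param sequence,proteins,reverse,contaminant column names.
#' @param intensity_prefix prefix identifying per-sample intensity columns;
#'   the sample id is the remainder of the column name.
#' @param flag_marker character marking a set flag cell.
#' @return A list of class `table_dialect`.
#' @export
maxquant_dialect <- function(sequence = "Sequence",
                             proteins = "Proteins",
                             reverse = "Reverse",
                             contaminant = "Potential contaminant",
                             intensity_prefix = "Intensity ",
                             flag_marker = "+") {
  structure(list(sequence = sequence, proteins = proteins,
                 reverse = reverse, contaminant = contaminant,
                 intensity_prefix = intensity_prefix,
                 flag_marker = flag_marker),
            class = "table_dialect")
}

#' Read a MaxQuant-style peptide identification table
#'
#' @param path path to a tab-separated table.
#' @param dialect a [maxquant_dialect()] column mapping.
#' @return A [peptide_table()]. Empty intensity cells are read as 0.
#' @export
read_peptide_table <- function(path, dialect = maxquant_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  for (role in c("sequence", "proteins", "reverse", "contaminant")) {
    if (!dialect[[role]] %in% names(df)) {
      stop(sprintf("format error: missing column '%s' (role: %s)",
                   dialect[[role]], role))
    }
  }
  int_cols <- names(df)[startsWith(names(df), dialect$intensity_prefix)]
  if (!length(int_cols)) {
    stop(sprintf("format error: no intensity columns with prefix '%s'",
                 dialect$intensity_prefix))
  }
  seqs <- toupper(df[[dialect$sequence]])
  bad <- which(!is_canonical_aa(seqs))
  if (length(bad)) {
    stop(sprintf("non-canonical amino acid in sequence at row(s): %s",
                 paste(utils::head(bad, 20L), collapse = ", ")))
  }
  samples <- substring(int_cols, nchar(dialect$intensity_prefix) + 1L)
  intensity <- vapply(int_cols, function(cl) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    v[is.na(v) | !nzchar(df[[cl]])] <- 0
    v
  }, numeric(nrow(df)))
  intensity <- matrix(intensity, nrow = nrow(df),
                      dimnames = list(NULL, samples))
  peptide_table(
    sequence = seqs,
    intensity = intensity,
    proteins = df[[dialect$proteins]],
    is_reverse = df[[dialect$reverse]] == dialect$flag_marker,
    is_contaminant = df[[dialect$contaminant]] == dialect$flag_marker
  )
}

#' Write a peptide table in the MaxQuant-style dialect
#'
#' Round-trips exactly through [read_peptide_table()].
#'
#' @param table a [peptide_table()].
#' @param path output path (TSV).
#' @param dialect a [maxquant_dialect()].
#' @export
write_peptide_table <- function(table, path, dialect = maxquant_dialect()) {
  stopifnot(inherits(table, "peptide_table"))
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = table$sequence,
    b = table$proteins,
    c = ifelse(table$is_reverse, dialect$flag_marker, ""),
    d = ifelse(table$is_contaminant, dialect$flag_marker, "")
  )
  names(df) <- c(dialect$sequence, dialect$proteins,
                 dialect$reverse, dialect$contaminant)
  ints <- as.data.frame(table$intensity, check.names = FALSE)
  names(ints) <- paste0(dialect$intensity_prefix, table$samples)
  utils::write.table(cbind(df, ints), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA database
#'
#' The accession is the header token before the first whitespace.
#'
#' @param path FASTA file path.
#' @return An object of class `protein_db`: a named character vector of
#'   canonical AA sequences, names = accessions.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("empty FASTA file")
  acc <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(acc)) {
    stop(sprintf("duplicate accession(s): %s",
                 paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  bad <- which(!is_canonical_aa(seqs))
  if (length(bad)) {
    stop(sprintf("non-canonical residue in entries: %s",
                 paste(acc[bad], collapse = ", ")))
  }
  protein_db(stats::setNames(seqs, acc))
}

#' Construct a protein database
#'
#' @param sequences named character vector, accession -> canonical sequence.
#' @return Object of class `protein_db`.
#' @export
protein_db <- function(sequences) {
  sequences <- unlist(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named by accession")
  }
  if (anyDuplicated(names(sequences))) stop("accessions must be unique")
  stop_noncanonical(sequences, "protein sequence")
  structure(sequences, class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db> %d proteins, %d residues total\n",
              length(x), sum(nchar(x))))
  invisible(x)
}

#' Write a protein database as FASTA
#'
#' @param db a [protein_db()].
#' @param path output path.
#' @export
write_fasta <- function(db, path) {
  lines <- as.vector(rbind(paste0(">", names(db)), unclass(db)))
  writeLines(lines, path)
  invisible(path)
}

#' Filter a peptide table
#'
#' Applies the standard post-search filter: decoy (reverse) hits are removed
#' first, then unambiguous contaminants, then peptides outside the length
#' range. A contaminant-flagged peptide is *unambiguous* when none of its
#' protein accessions points to a target protein (all are empty or carry the
#' `CON__`/`REV__` prefix); ambiguous contaminants, which also map to a
#' target protein, are retained. A filter report (counts removed per reason)
#' is attached as attribute `"filter_report"`.
#'
#' @param table a [peptide_table()].
#' @param min_len,max_len retained peptide length range (residues),
#'   inclusive. Defaults 3 and 65, the identifiable range of an unspecific
#'   bottom-up search.
#' @param drop_flags drop reverse/contaminant-flagged peptides.
#' @return A filtered [peptide_table()]; the input is unmodified.
#' @export
filter_peptides <- function(table, min_len = 3L, max_len = 65L,
                            drop_flags = TRUE) {
  stopifnot(inherits(table, "peptide_table"),
            min_len >= 1L, max_len >= min_len)
  n <- length(table$sequence)
  keep <- rep(TRUE, n)
  removed_reverse <- removed_contaminant <- 0L
  if (drop_flags) {
    rev_drop <- keep & table$is_reverse
    removed_reverse <- sum(rev_drop)
    keep <- keep & !rev_drop
    has_target <- vapply(strsplit(table$proteins, ";", fixed = TRUE),
                         function(acc) {
                           acc <- acc[nzchar(acc)]
                           any(!grepl("^(CON__|REV__)", acc))
                         }, logical(1))
    con_drop <- keep & table$is_contaminant & !has_target
    removed_contaminant <- sum(con_drop)
    keep <- keep & !con_drop
  }
  len <- nchar(table$sequence)
  len_drop <- keep & (len < min_len | len > max_len)
  removed_length <- sum(len_drop)
  keep <- keep & !len_drop
  out <- subset_peptide_table(table, keep)
  attr(out, "filter_report") <- list(
    input = n,
    retained = sum(keep),
    removed = list(reverse = removed_reverse,
                   contaminant = removed_contaminant,
                   length = removed_length),
    min_len = min_len, max_len = max_len, drop_flags = drop_flags
  )
  out
}

#' @rdname filter_peptides
#' @export
filter_report <- function(table) attr(table, "filter_report")
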