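#' @keywords internal
"_PACKAGE"

# Canonical amino-acid alphabet (one-letter codes), alphabetical.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses (Da); peptide mass = sum + one water.
AA_AVG_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.0153

#' Check sequences for canonical amino-acid letters
#'
#' @param sequences character vector of peptide/protein sequences.
#' @return logical vector, `TRUE` where the sequence is a non-empty string of
#'   the 20 canonical one-letter amino-acid codes.
#' @keywords internal
is_canonical_aa <- function(sequences) {
  nzchar(sequences) & !grepl(sprintf("[^%s]", paste(AA_LETTERS, collapse = "")),
                             sequences)
}

stop_noncanonical <- function(sequences, what = "sequence") {
  bad <- which(!is_canonical_aa(sequences))
  if (length(bad)) {
    stop(sprintf(
      "non-canonical or empty %s at position(s): %s",
      what, paste(utils::head(bad, 10L), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(sequences)
}

#' Residue count matrix
#'
#' Counts each canonical residue in each sequence.
#'
#' @param sequences character vector of canonical AA sequences.
#' @return integer matrix with one row per sequence and the 20 canonical
#'   amino acids as columns.
#' @keywords internal
aa_count_matrix <- function(sequences) {
  stop_noncanonical(sequences)
  chars <- strsplit(sequences, "", fixed = TRUE)
  counts <- t(vapply(
    chars,
    function(ch) tabulate(factor(ch, levels = AA_LETTERS), nbins = 20L),
    integer(20L)
  ))
  colnames(counts) <- AA_LETTERS
  counts
}

# Evaluate expr with a private RNG stream; global .Random.seed is restored.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}
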