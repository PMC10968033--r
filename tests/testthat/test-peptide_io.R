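toy_tsv <- function(path,
                    rows = c("PEPTIDE\tsp|P1|X\t\t\t100",
                             "GGKAA\tsp|P2|Y\t+\t\t200",
                             "AAL\tCON__P3\t\t+\t"),
                    header = "Sequence\tProteins\tReverse\tPotential contaminant\tIntensity A") {
  writeLines(c(header, rows), path)
  path
}

test_that("read_peptide_table parses the MaxQuant dialect", {
  path <- toy_tsv(withr::local_tempfile(fileext = ".tsv"))
  tab <- read_peptide_table(path)
  expect_s3_class(tab, "peptide_table")
  expect_length(tab, 3)
  expect_identical(tab$samples, "A")
  expect_identical(tab$sequence, c("PEPTIDE", "GGKAA", "AAL"))
  expect_identical(tab$is_reverse, c(FALSE, TRUE, FALSE))
  expect_identical(tab$is_contaminant, c(FALSE, FALSE, TRUE))
  # empty intensity cell reads as 0
  expect_equal(unname(tab$intensity[, "A"]), c(100, 200, 0))
})

test_that("read_peptide_table reports format and row-level errors", {
  bad_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Seq\tProteins\tReverse\tPotential contaminant\tIntensity A",
               "PEP\tp\t\t\t1"), bad_col)
  expect_error(read_peptide_table(bad_col), "missing column 'Sequence'")

  bad_row <- toy_tsv(withr::local_tempfile(fileext = ".tsv"),
                     rows = c("PEPTIDE\tp\t\t\t1", "PEPZ\tp\t\t\t1"))
  expect_error(read_peptide_table(bad_row), "row\\(s\\): 2")
  expect_error(read_peptide_table(withr::local_tempfile()), "not found")
})

test_that("peptide tables round-trip through write/read exactly", {
  set.seed(41)
  tab <- random_peptide_table(50, n_samples = 3)
  tab$is_reverse[c(2, 7)] <- TRUE
  tab$is_contaminant[5] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_table(tab, path)
  back <- read_peptide_table(path)
  expect_identical(back$sequence, tab$sequence)
  expect_identical(back$is_reverse, tab$is_reverse)
  expect_identical(back$is_contaminant, tab$is_contaminant)
  expect_identical(back$samples, tab$samples)
  expect_equal(back$intensity, tab$intensity, tolerance = 1e-12)
})

test_that("read_fasta applies the accession convention and validates", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|X some description", "PEPTIDE", ">P2", "GGKAA"), fa)
  db <- read_fasta(fa)
  expect_s3_class(db, "protein_db")
  expect_length(db, 2)
  expect_identical(names(db), c("sp|P1|X", "P2"))

  writeLines(c(">A", "PEPZIDE"), fa)
  expect_error(read_fasta(fa), "non-canonical residue.*A")
  writeLines(c(">A", "PEP", ">A", "GGG"), fa)
  expect_error(read_fasta(fa), "duplicate accession")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "empty")
})

test_that("filter_peptides removes flags and out-of-range lengths", {
  tab <- peptide_table(
    sequence = c("AAA", "CC", replicate(6, paste(sample(AA20, 10,
                  replace = TRUE), collapse = "")), "KKK", "RRR"),
    intensity = matrix(1, nrow = 10, ncol = 1,
                       dimnames = list(NULL, "A")),
    is_reverse = c(rep(FALSE, 8), TRUE, TRUE),
    is_contaminant = c(FALSE, FALSE, TRUE, rep(FALSE, 7))
  )
  out <- filter_peptides(tab)
  expect_length(out, 6)   # 2 reverse + 1 contaminant + 1 dipeptide removed
  rpt <- filter_report(out)
  expect_equal(rpt$removed$reverse, 2)
  expect_equal(rpt$removed$contaminant, 1)
  expect_equal(rpt$removed$length, 1)
  expect_equal(rpt$retained + Reduce(`+`, rpt$removed), rpt$input)
})

test_that("length bounds are inclusive at 65 and exclusive above", {
  tab <- peptide_table(
    sequence = c(strrep("A", 65), strrep("A", 66), strrep("A", 3),
                 strrep("A", 2)),
    intensity = matrix(1, 4, 1, dimnames = list(NULL, "A")))
  out <- filter_peptides(tab)
  expect_setequal(nchar(out$sequence), c(65, 3))
})

test_that("ambiguous contaminants (with a target protein) are retained", {
  tab <- peptide_table(
    sequence = c("AAAA", "CCCC", "DDDD"),
    intensity = matrix(1, 3, 1, dimnames = list(NULL, "A")),
    proteins = c("CON__X", "CON__X;sp|P1|Y", ""),
    is_contaminant = c(TRUE, TRUE, TRUE))
  out <- filter_peptides(tab)
  expect_identical(out$sequence, "CCCC")
  expect_equal(filter_report(out)$removed$contaminant, 2)
})

test_that("filter_peptides is idempotent and handles empty tables", {
  set.seed(7)
  tab <- random_peptide_table(40)
  tab$is_reverse[1:5] <- TRUE
  once <- filter_peptides(tab)
  twice <- filter_peptides(once)
  expect_identical(twice$sequence, once$sequence)
  expect_identical(twice$intensity, once$intensity)
  expect_equal(Reduce(`+`, filter_report(twice)$removed), 0)

  empty <- subset_empty <- filter_peptides(
    peptide_table(character(0),
                  matrix(numeric(0), 0, 1, dimnames = list(NULL, "A"))))
  expect_length(empty, 0)
  expect_equal(filter_report(empty)$input, 0)
})
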