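test_that("make_protein_db is deterministic and respects its contract", {
  db1 <- make_protein_db(3, seed = 7)
  db2 <- make_protein_db(3, seed = 7)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db1, f1)
  write_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(unclass(db1),
                         unclass(make_protein_db(3, seed = 8))))

  db <- make_protein_db(40, mean_length = 300, length_sd = 10, seed = 2)
  expect_true(all(abs(nchar(db) - 300) <= 3 * 10 + 10))
})

test_that("generated composition matches the target frequencies", {
  db <- make_protein_db(170, mean_length = 300, seed = 5)
  residues <- sum(nchar(db))
  expect_gt(residues, 5e4)
  counts <- colSums(aa_count_matrix(unclass(db)))
  freq <- hydroscreen:::POTATO_AA_FREQ[names(counts)]
  p <- suppressWarnings(chisq.test(counts, p = freq)$p.value)
  expect_gt(p, 0.01)
})

test_that("digest applies endoprotease rules exactly at p_cut = 1", {
  db <- protein_db(c(P1 = "AKGRMP"))
  state <- digest(db, rule_trypsin(), seed = 1)
  expect_setequal(state$pool$sequence, c("AK", "GR", "MP"))
  expect_equal(state$cleaved_bonds, 2)
  expect_equal(state$total_bonds, 5)
  expect_equal(true_dh(state), 40)

  blocked <- digest(protein_db(c(P1 = "AKPG")), rule_trypsin(), seed = 1)
  expect_equal(nrow(blocked$pool), 1)
  expect_equal(true_dh(blocked), 0)
})

test_that("partial cleavage hits the expected bond fraction", {
  # substrate with 10 eligible K bonds, 1000 copies
  db <- protein_db(c(P1 = paste(rep("KAA", 10), collapse = "")))
  rule <- enzyme_rule("halfcut", "K", p_cut = 0.5)
  fracs <- vapply(1:5, function(s) {
    st <- digest(db, rule, seed = s, copies = 1000)
    st$cleaved_bonds / (10 * 1000)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.03)
})

test_that("sequential digestion accumulates and never decreases DH", {
  db <- make_protein_db(4, mean_length = 200, seed = 3)
  noop <- enzyme_rule("noop", "K", p_cut = 0)
  s1 <- digest(db, rule_trypsin(), seed = 5)
  s2 <- sequential_digest(db, list(rule_trypsin(), noop), seed = 5)
  expect_identical(s2$cleaved_bonds, s1$cleaved_bonds)
  expect_setequal(s2$pool$sequence, s1$pool$sequence)

  for (seed in 1:5) {
    st <- sequential_digest(db, list(rule_alcalase(), rule_flavourzyme()),
                            seed = seed)
    dh <- attr(st, "stage_dh")
    expect_true(all(diff(dh) >= 0))
    expect_equal(dh[length(dh)], true_dh(st))
  }
})

test_that("exopeptidase trimming releases free amino acids and counts bonds", {
  db <- protein_db(c(P1 = "ACDEFG"))
  exo <- enzyme_rule("exo", character(0), p_cut = 0,
                     exo_n_trim_prob = 1, exo_rounds = 3L)
  st <- digest(db, exo, seed = 1)
  expect_equal(true_dh(st), 100 * 3 / 5)
  expect_setequal(st$pool$sequence, c("A", "C", "D", "EFG"))
  # residue conservation
  expect_equal(sum(st$pool$amount * nchar(st$pool$sequence)),
               st$substrate_residues)
})

test_that("peptide_mass uses average residue masses plus water", {
  expect_equal(peptide_mass("GG"), 132.12, tolerance = 1e-2)
  expect_error(peptide_mass(""), "non-canonical")
  set.seed(9)
  for (seq in random_sequences(10)) {
    heavier <- peptide_mass(paste0(seq, "G"))
    expect_gt(heavier, peptide_mass(seq))
  }
})

test_that("ultrafilter partitions by mass and conserves amount", {
  db <- make_protein_db(5, mean_length = 250, seed = 11)
  st <- digest(db, rule_alcalase(0.3), seed = 11, copies = 3)
  exact <- ultrafilter(st, leak_prob = 0, seed = 1)
  for (label in names(exact)) {
    m <- peptide_mass(exact[[label]]$sequence)
    if (label == "<1 kDa") expect_true(all(m <= 1000))
    if (label == "3-5 kDa") expect_true(all(m > 3000 & m <= 5000))
  }
  for (seed in 1:5) {
    fr <- ultrafilter(st, leak_prob = 0.3, seed = seed)
    total <- sum(vapply(fr, function(p) sum(p$amount), numeric(1)))
    expect_equal(total, sum(st$pool$amount), tolerance = 1e-9)
  }
})

test_that("imperfect separation leaves short peptides in high-MW fractions", {
  hits <- vapply(1:20, function(seed) {
    db <- make_protein_db(5, mean_length = 250, seed = seed)
    st <- digest(db, rule_alcalase(0.25), seed = seed, copies = 3)
    fr <- ultrafilter(st, leak_prob = 0.3, seed = seed)
    wlen <- function(p) sum(p$amount * nchar(p$sequence)) / sum(p$amount)
    f35 <- fr[["3-5 kDa"]]
    has_shorts <- any(nchar(f35$sequence) <= 9)
    wlen(f35) > wlen(fr[["<1 kDa"]]) && has_shorts
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("ms_observe respects the detection floor and Lys boost", {
  dipeptides <- data.frame(sequence = c("AA", "GG"), amount = c(5, 5))
  empty <- ms_observe(dipeptides, seed = 1)
  expect_length(empty, 0)

  pool <- data.frame(sequence = c("AAAAA", "AAKAA"), amount = c(10, 10))
  params <- observation_params(noise_cv = 0,
                               length_detect_curve = function(l) rep(1, length(l)))
  tab <- ms_observe(pool, params, seed = 1)
  i <- tab$intensity[, 1]
  expect_equal(i[tab$sequence == "AAKAA"] / i[tab$sequence == "AAAAA"], 1.5,
               ignore_attr = TRUE)
})

test_that("Lys-containing peptides are over-represented after observation", {
  hits <- vapply(1:20, function(seed) {
    db <- make_protein_db(4, mean_length = 200, seed = seed)
    st <- sequential_digest(db, list(rule_alcalase(), rule_flavourzyme()),
                            seed = seed, copies = 3)
    pool <- st$pool
    keep <- nchar(pool$sequence) >= 3 & nchar(pool$sequence) <= 65
    pool <- pool[keep, ]
    tab <- ms_observe(pool, observation_params(noise_cv = 0.2), seed = seed)
    if (length(tab) < 10) return(NA)
    obs_k <- aa_molar_abundance(tab, tab$samples)[["K"]]
    counts <- aa_count_matrix(pool$sequence)
    pool_k <- sum(pool$amount * counts[, "K"]) /
      sum(pool$amount * nchar(pool$sequence))
    obs_k > pool_k
  }, logical(1))
  expect_gt(mean(hits, na.rm = TRUE), 0.5)
})

test_that("synth_scores honors range, determinism and composition effects", {
  seqs <- c("AAA", strrep("A", 31), "WYF")
  st <- synth_scores(seqs, seed = 1)
  expect_false(strrep("A", 31) %in% st$sequence)
  st2 <- synth_scores(seqs, seed = 1)
  expect_identical(st, st2)

  set.seed(21)
  arom_short <- vapply(1:60, function(i) paste(
    sample(c("F", "W", "Y", "H", "G"), 4, TRUE), collapse = ""), character(1))
  ali_long <- vapply(1:60, function(i) paste(
    sample(c("A", "L", "V", "I", "G"), 25, TRUE), collapse = ""), character(1))
  diffs <- vapply(1:20, function(seed) {
    sa <- synth_scores(unique(arom_short), seed = seed)
    sl <- synth_scores(unique(ali_long), seed = seed + 1000)
    mean(sa$che) - mean(sl$che)
  }, numeric(1))
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("synth_isotherm produces the stated design and round-trips", {
  iso <- synth_isotherm(1, 100)
  expect_equal(nrow(iso), 10)  # 7 concentrations + duplicates of 1st/4th/7th
  expect_equal(sum(iso$concentration == 0.25), 2)
  expect_equal(sum(iso$concentration == 2), 2)
  expect_equal(sum(iso$concentration == 10), 2)
  fit <- fit_langmuir(iso)
  expect_equal(fit$kd, 1, tolerance = 1e-6)
  expect_equal(fit$rmax, 100, tolerance = 1e-6)
})

test_that("synth_opa_plate is monotone in dilution and deterministic", {
  curve <- calibration_curve(1.2, 0.02, "serine")
  p1 <- synth_opa_plate(38.8, 0.2, curve, noise_cv = 0.02, seed = 5)
  p2 <- synth_opa_plate(38.8, 0.2, curve, noise_cv = 0.02, seed = 5)
  expect_identical(p1, p2)
  noiseless <- synth_opa_plate(38.8, 0.2, curve, noise_cv = 0, seed = 1)
  mean_abs <- tapply(noiseless$absorbance, noiseless$df, mean)
  expect_true(all(diff(mean_abs[order(as.numeric(names(mean_abs)))]) < 0))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_protein_db(2, seed = 9))
  invisible(synth_isotherm(1, 10, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("pool_affinity_kd weakens with mean length and is capped", {
  short_pool <- data.frame(sequence = rep("AAAA", 5), amount = 1)
  long_pool <- data.frame(sequence = rep(strrep("A", 12), 5), amount = 1)
  expect_lt(pool_affinity_kd(short_pool), pool_affinity_kd(long_pool))
  huge <- data.frame(sequence = strrep("A", 60), amount = 1)
  expect_equal(pool_affinity_kd(huge), 20)
})
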