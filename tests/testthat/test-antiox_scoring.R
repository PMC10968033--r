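scored_fixture <- function(n = 50, seed = 17) {
  set.seed(seed)
  tab <- random_peptide_table(n)
  scores <- score_table(tab$sequence, frs = runif(n), che = runif(n))
  attach_scores(tab, scores)
}

test_that("attach_scores respects the scorable length range", {
  tab <- peptide_table(c("AAA", strrep("A", 31)),
                       matrix(c(1, 1), 2, 1, dimnames = list(NULL, "A")))
  scores <- score_table("AAA", frs = 0.5, che = 0.5)
  out <- attach_scores(tab, scores)
  expect_equal(out$frs, c(0.5, NA))
  cov <- attr(out, "score_coverage")
  expect_equal(cov$n_scored, 1)
  expect_equal(cov$unscored_intensity_share[["A"]], 0.5)
})

test_that("full coverage and empty score tables behave", {
  st <- scored_fixture()
  expect_equal(attr(st, "score_coverage")$coverage, 1)

  tab <- peptide_table("AAA", matrix(1, 1, 1, dimnames = list(NULL, "A")))
  empty <- score_table(character(0), numeric(0), numeric(0))
  out <- attach_scores(tab, empty)
  expect_true(all(is.na(out$frs)))
  expect_error(aggregate_scores(out, "A", "FRS"), "no scored")
})

test_that("score_table validates its invariants", {
  expect_error(score_table("AAA", 1.2, 0.5), "\\[0, 1\\]")
  expect_error(score_table(strrep("A", 31), 0.5, 0.5), "3-30")
  expect_error(score_table(c("AAA", "AAA"), c(.1, .2), c(.1, .2)),
               "duplicate")
})

test_that("aggregate_scores computes threshold shares", {
  tab <- peptide_table(c("AAA", "CCC"),
                       matrix(c(5, 5), 2, 1, dimnames = list(NULL, "A")))
  scores <- score_table(c("AAA", "CCC"), frs = c(0.2, 0.4),
                        che = c(0.2, 0.4))
  st <- attach_scores(tab, scores)
  agg <- aggregate_scores(st, "A", "CHE")
  expect_equal(agg$intensity_frac_above, 0.5)
  expect_equal(agg$n_above, 1)
  # inclusive threshold
  agg_inc <- aggregate_scores(st, "A", "CHE",
                              threshold_config(che_threshold = 0.4))
  expect_equal(agg_inc$intensity_frac_above, 0.5)
  # threshold 0 captures everything
  agg0 <- aggregate_scores(st, "A", "CHE",
                           threshold_config(che_threshold = 0))
  expect_equal(agg0$intensity_frac_above, 1)
})

test_that("intensity_frac_above is non-increasing in the threshold", {
  st <- scored_fixture(200, seed = 29)
  vals <- vapply(seq(0, 1, by = 0.1), function(t) {
    aggregate_scores(st, "S1", "FRS",
                     threshold_config(frs_threshold = t))$intensity_frac_above
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_equal(vals[1], 1)
})

test_that("aggregate_scores matches the loop oracle and is invariant", {
  set.seed(101)
  n <- 500
  tab <- random_peptide_table(n)
  scores <- score_table(tab$sequence, runif(n), runif(n))
  st <- attach_scores(tab, scores)
  for (prop in c("FRS", "CHE")) {
    t <- if (prop == "FRS") 0.43 else 0.30
    expect_equal(aggregate_scores(st, "S1", prop)$intensity_frac_above,
                 oracle_aggregate(st, "S1", prop, t), tolerance = 1e-12)
  }
  # order and scale invariance
  perm <- sample(n)
  tab_perm <- peptide_table(tab$sequence[perm],
                            tab$intensity[perm, , drop = FALSE])
  st_perm <- attach_scores(tab_perm, scores)
  st_scaled <- attach_scores(
    peptide_table(tab$sequence, tab$intensity * 77), scores)
  base <- aggregate_scores(st, "S1", "CHE")$intensity_frac_above
  expect_equal(aggregate_scores(st_perm, "S1", "CHE")$intensity_frac_above,
               base, tolerance = 1e-12)
  expect_equal(aggregate_scores(st_scaled, "S1", "CHE")$intensity_frac_above,
               base, tolerance = 1e-12)
})

test_that("compare_score_means detects separated groups", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- compare_score_means(g)
  expect_lt(res$f_statistic, 1e-10)
  expect_gt(res$tukey$p_adj[1], 0.999)

  set.seed(2)
  res2 <- compare_score_means(list(a = rnorm(50), b = rnorm(50, 5)))
  expect_lt(res2$p_value, 1e-3)
  expect_lt(res2$tukey$p_adj[1], 1e-3)

  expect_error(compare_score_means(list(1:3)), "at least 2 groups")
  expect_error(compare_score_means(list(a = 1, b = 1:3)), "at least 2 values")
})

test_that("only pairs involving a shifted group are significant (majority)", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    g <- list(a = rnorm(100), b = rnorm(100), c = rnorm(100, 1))
    tk <- compare_score_means(g)$tukey
    shifted <- grepl("c", tk$pair)
    all(tk$p_adj[shifted] < 0.05) && all(tk$p_adj[!shifted] >= 0.05)
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("overlap_analysis decomposes exclusive intersections", {
  res <- overlap_analysis(list(s1 = c("A", "B", "C"), s2 = c("B", "C"),
                               s3 = "C"))
  expect_equal(res$conserved, 1)
  expect_equal(res$unique_counts[["s1"]], 1)
  pat <- res$patterns
  expect_equal(pat$count[pat$s1 & pat$s2 & !pat$s3], 1)  # exactly {B}
  expect_equal(sum(pat$count), res$n_union)

  same <- overlap_analysis(list(a = letters[1:5], b = letters[1:5]))
  expect_equal(same$conserved, 5)
  expect_equal(nrow(same$patterns), 1)
})

test_that("overlap_analysis matches the membership-pattern oracle", {
  set.seed(13)
  universe <- unique_random_sequences(200)
  sets <- lapply(1:5, function(i) sample(universe, sample(50:150, 1)))
  names(sets) <- paste0("f", 1:5)
  res <- overlap_analysis(sets)
  expect_equal(sum(res$patterns$count), length(unique(unlist(sets))))
  oracle <- oracle_overlap(sets)
  for (i in seq_len(nrow(res$patterns))) {
    key <- paste(unlist(res$patterns[i, names(sets)]) * 1L, collapse = "")
    expect_equal(res$patterns$count[i], oracle[[key]])
  }
})

test_that("collapse_sequences sums intensities over duplicates", {
  tab <- peptide_table(c("AAA", "CCC", "AAA"),
                       matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "A")))
  out <- collapse_sequences(tab)
  expect_length(out, 2)
  expect_equal(out$intensity[out$sequence == "AAA", "A"], c(4),
               ignore_attr = TRUE)
})
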