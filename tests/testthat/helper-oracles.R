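# Independent brute-force oracles and random fixtures. Every oracle is a
# plain double loop / enumeration, deliberately ignorant of the package's
# vectorized implementations.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_sequences <- function(n, min_len = 3, max_len = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(AA20, sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

random_peptide_table <- function(n, n_samples = 2, zero_frac = 0.1) {
  intensity <- matrix(stats::rexp(n * n_samples, rate = 1e-6),
                      ncol = n_samples,
                      dimnames = list(NULL, paste0("S", seq_len(n_samples))))
  intensity[stats::runif(n * n_samples) < zero_frac] <- 0
  # keep each sample quantified
  intensity[1, ] <- pmax(intensity[1, ], 1)
  peptide_table(sequence = unique_random_sequences(n),
                intensity = intensity)
}

unique_random_sequences <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, random_sequences(n)))
  }
  out[seq_len(n)]
}

charge_contrib <- c(D = -1, E = -1, R = 1, K = 1, H = 0.1)

oracle_charge <- function(seq) {
  total <- 0
  for (ch in strsplit(seq, "")[[1]]) {
    if (ch %in% names(charge_contrib)) total <- total + charge_contrib[[ch]]
  }
  total
}

oracle_aa_abundance <- function(table, sample) {
  ints <- table$intensity[, sample]
  w <- ints / sum(ints)
  num <- stats::setNames(numeric(20), AA20)
  den <- 0
  for (i in seq_along(table$sequence)) {
    chars <- strsplit(table$sequence[i], "")[[1]]
    for (ch in chars) num[ch] <- num[ch] + w[i]
    den <- den + w[i] * length(chars)
  }
  num / den
}

oracle_summary <- function(table, sample) {
  ints <- table$intensity[, sample]
  w <- ints / sum(ints)
  n <- length(table$sequence)
  lens <- charges <- numeric(n)
  for (i in seq_len(n)) {
    lens[i] <- nchar(table$sequence[i])
    charges[i] <- oracle_charge(table$sequence[i])
  }
  list(
    n_peptide_ids = n,
    mean_length = sum(lens) / n,
    weighted_mean_length = sum(w * lens),
    mean_charge = sum(charges) / n,
    weighted_mean_charge = sum(w * charges),
    aa_abundance = oracle_aa_abundance(table, sample)
  )
}

oracle_aggregate <- function(table, sample, property, threshold) {
  score <- if (property == "FRS") table$frs else table$che
  ints <- table$intensity[, sample]
  num <- den <- 0
  for (i in seq_along(score)) {
    if (!is.na(score[i]) && ints[i] > 0) {
      den <- den + ints[i]
      if (score[i] >= threshold) num <- num + ints[i]
    }
  }
  num / den
}

oracle_overlap <- function(sets) {
  universe <- unique(unlist(sets))
  counts <- new.env()
  for (el in universe) {
    pattern <- paste(vapply(sets, function(s) el %in% s, logical(1)) * 1L,
                     collapse = "")
    counts[[pattern]] <- (counts[[pattern]] %||% 0L) + 1L
  }
  as.list(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-D log-grid search for the Langmuir K_D; R_max given K_D is the
# closed-form conditional least-squares optimum.
oracle_langmuir_grid <- function(conc, resp, kd_lo = 0.01, kd_hi = 100,
                                 n_grid = 600) {
  kd_grid <- exp(seq(log(kd_lo), log(kd_hi), length.out = n_grid))
  sse <- vapply(kd_grid, function(kd) {
    f <- conc / (kd + conc)
    rmax <- sum(f * resp) / sum(f * f)
    sum((resp - rmax * f)^2)
  }, numeric(1))
  best <- which.min(sse)
  list(kd = kd_grid[best],
       grid_step = log(kd_grid[2]) - log(kd_grid[1]))
}

# brute-force tryptic digest (full cleavage C-terminal to K/R, no Pro block)
oracle_trypsin_fragments <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  frags <- character(0)
  current <- ""
  for (i in seq_along(chars)) {
    current <- paste0(current, chars[i])
    if (chars[i] %in% c("K", "R") && i < length(chars)) {
      frags <- c(frags, current)
      current <- ""
    }
  }
  c(frags, current)
}
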