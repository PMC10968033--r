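# Synthetic hydrolysate study generator: sequential enzymatic digestion
# with ground-truth degree of hydrolysis, ultrafiltration into
# molecular-weight fractions, biased MS observation, antioxidant score
# tables, Langmuir isotherms and OPA plates. All generators are pure
# functions of (parameters, seed).

# Potato-protein-like residue frequencies (patatin/protease-inhibitor rich
# isolates are Lys- and Leu-rich). Configurable; a stand-in, not a claim.
POTATO_AA_FREQ <- c(
  A = 0.055, C = 0.012, D = 0.065, E = 0.075, F = 0.050,
  G = 0.070, H = 0.020, I = 0.050, K = 0.060, L = 0.095,
  M = 0.020, N = 0.045, P = 0.055, Q = 0.040, R = 0.045,
  S = 0.065, T = 0.050, V = 0.070, W = 0.012, Y = 0.040
)
POTATO_AA_FREQ <- POTATO_AA_FREQ / sum(POTATO_AA_FREQ)

#' Protease cleavage rule
#'
#' A terminal-state bond-sampling model of one hydrolysis stage: an
#' endoprotease component cleaves C-terminal to `p1_residues` (each eligible
#' bond independently with probability `p_cut`), optionally blocked by a
#' P1' proline; an exopeptidase component then trims N-terminal residues
#' (per peptide, `exo_rounds` rounds, each removing the terminal residue
#' with probability `exo_n_trim_prob` and releasing a free amino acid).
#'
#' @param name label.
#' @param p1_residues P1 residues (cleavage C-terminal to these).
#' @param p_cut per-bond cleavage probability in `[0, 1]`.
#' @param block_p1prime_pro suppress cleavage when the following residue is
#'   proline.
#' @param exo_n_trim_prob,exo_rounds exopeptidase trimming parameters.
#' @return Object of class `enzyme_rule`.
#' @export
enzyme_rule <- function(name, p1_residues = character(), p_cut = 0,
                        block_p1prime_pro = FALSE,
                        exo_n_trim_prob = 0, exo_rounds = 0L) {
  stopifnot(p_cut >= 0, p_cut <= 1,
            exo_n_trim_prob >= 0, exo_n_trim_prob <= 1)
  if (!length(p1_residues) && p_cut > 0) {
    stop("p1_residues must be non-empty unless the rule is pure exo")
  }
  if (length(p1_residues) && !all(p1_residues %in% AA_LETTERS)) {
    stop("p1_residues must be canonical amino-acid letters")
  }
  structure(list(name = name, p1_residues = p1_residues, p_cut = p_cut,
                 block_p1prime_pro = block_p1prime_pro,
                 exo_n_trim_prob = exo_n_trim_prob,
                 exo_rounds = as.integer(exo_rounds)),
            class = "enzyme_rule")
}

#' Stock enzyme rules
#'
#' Stand-in specificity models for the three enzymes of the two-stage
#' digestion design. Trypsin cleaves C-terminal to Arg/Lys (proline block
#' on); "alcalase" is a broad-specificity endoprotease; "flavourzyme" is a
#' moderate broad endoprotease plus N-terminal exopeptidase trimming.
#' `p_cut` values are calibrated so a substrate with the default
#' composition reaches a stage-1 DH near 20% (alcalase) or 13% (trypsin),
#' rising to roughly 35-40% after the flavourzyme stage.
#'
#' @name stock_rules
NULL

BROAD_P1 <- c("A", "F", "L", "M", "W", "Y", "V", "E", "Q", "S")

#' @rdname stock_rules
#' @param p_cut per-bond cleavage probability.
#' @export
rule_trypsin <- function(p_cut = 1) {
  enzyme_rule("trypsin", c("K", "R"), p_cut, block_p1prime_pro = TRUE)
}

#' @rdname stock_rules
#' @export
rule_alcalase <- function(p_cut = 0.40) {
  enzyme_rule("alcalase", BROAD_P1, p_cut)
}

#' @rdname stock_rules
#' @param exo_n_trim_prob,exo_rounds exopeptidase trimming parameters.
#' @export
rule_flavourzyme <- function(p_cut = 0.12, exo_n_trim_prob = 0.32,
                             exo_rounds = 2L) {
  enzyme_rule("flavourzyme", BROAD_P1, p_cut,
              exo_n_trim_prob = exo_n_trim_prob, exo_rounds = exo_rounds)
}

#' Generate a random protein database
#'
#' Reproducible random substrate proteins with a configurable (by default
#' potato-like) residue frequency profile.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param mean_length mean protein length (residues).
#' @param length_sd sd of protein length.
#' @param seed RNG seed.
#' @param aa_freq named residue frequency vector over the 20 canonical AAs.
#' @return A [protein_db()].
#' @export
make_protein_db <- function(n_proteins, mean_length = 300, length_sd = 30,
                            seed = 1L, aa_freq = POTATO_AA_FREQ) {
  stopifnot(n_proteins >= 1)
  aa_freq <- aa_freq[AA_LETTERS]
  aa_freq <- aa_freq / sum(aa_freq)
  with_seed(seed, {
    lens <- pmax(30L, round(stats::rnorm(n_proteins, mean_length, length_sd)))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_LETTERS, L, replace = TRUE, prob = aa_freq),
            collapse = "")
    }, character(1))
    protein_db(stats::setNames(seqs, sprintf("SYN%04d", seq_len(n_proteins))))
  })
}

new_digest_state <- function(pool_seqs, cleaved, total, substrate_residues,
                             seed) {
  agg <- tapply(rep(1, length(pool_seqs)), pool_seqs, sum)
  structure(list(
    pool = data.frame(sequence = names(agg), amount = as.numeric(agg),
                      stringsAsFactors = FALSE, row.names = NULL),
    cleaved_bonds = cleaved,
    total_bonds = total,
    substrate_residues = substrate_residues,
    rng_seed = seed
  ), class = "digest_state")
}

#' @export
print.digest_state <- function(x, ...) {
  cat(sprintf(
    "<digest_state> %d distinct peptides (%.0f units); DH %.1f%% (%d/%d bonds)\n",
    nrow(x$pool), sum(x$pool$amount), true_dh(x),
    x$cleaved_bonds, x$total_bonds))
  invisible(x)
}

# Apply one enzyme rule to a character vector of peptide instances.
# Returns list(instances, cleaved) where cleaved counts newly broken bonds.
apply_rule_to_instances <- function(instances, rule) {
  cleaved <- 0L
  # endo phase
  if (rule$p_cut > 0 && length(rule$p1_residues)) {
    pieces <- lapply(strsplit(instances, "", fixed = TRUE), function(ch) {
      L <- length(ch)
      if (L < 2L) return(paste(ch, collapse = ""))
      eligible <- which(ch[-L] %in% rule$p1_residues)
      if (rule$block_p1prime_pro && length(eligible)) {
        eligible <- eligible[ch[eligible + 1L] != "P"]
      }
      if (!length(eligible)) return(paste(ch, collapse = ""))
      cut <- eligible[stats::runif(length(eligible)) < rule$p_cut]
      if (!length(cut)) return(paste(ch, collapse = ""))
      starts <- c(1L, cut + 1L)
      ends <- c(cut, L)
      substring(paste(ch, collapse = ""), starts, ends)
    })
    cleaved <- cleaved + sum(lengths(pieces)) - length(pieces)
    instances <- unlist(pieces, use.names = FALSE)
  }
  # exo phase: N-terminal trimming, releasing free AAs
  if (rule$exo_n_trim_prob > 0 && rule$exo_rounds > 0) {
    released <- character(0)
    for (round in seq_len(rule$exo_rounds)) {
      len <- nchar(instances)
      trim <- len > 1L & stats::runif(length(instances)) < rule$exo_n_trim_prob
      if (!any(trim)) next
      released <- c(released, substring(instances[trim], 1L, 1L))
      instances[trim] <- substring(instances[trim], 2L)
      cleaved <- cleaved + sum(trim)
    }
    instances <- c(instances, released)
  }
  list(instances = instances, cleaved = cleaved)
}

expand_instances <- function(pool) {
  rep(pool$sequence, times = pool$amount)
}

#' Digest a protein database with one enzyme rule
#'
#' Simulates terminal-state hydrolysis of `copies` molecules of each
#' substrate protein: every eligible bond is cleaved independently with the
#' rule's probability, then the exopeptidase component trims N-terminal
#' residues. Bond accounting gives the ground-truth degree of hydrolysis.
#'
#' @param db a [protein_db()].
#' @param rule an [enzyme_rule()].
#' @param seed RNG seed.
#' @param copies molecule copies per protein entry (molar units).
#' @return Object of class `digest_state`: peptide pool (sequence, molar
#'   amount), cleaved/total bond counts, substrate residue total, seed.
#' @export
digest <- function(db, rule, seed = 1L, copies = 1L) {
  sequential_digest(db, list(rule), seed = seed, copies = copies)
}

#' Sequential multi-enzyme digestion
#'
#' Applies each rule in order to the evolving peptide pool (the second
#' enzyme acts on the first stage's fragments); bond accounting is
#' cumulative, so ground-truth DH is non-decreasing across stages.
#'
#' @inheritParams digest
#' @param rules ordered list of [enzyme_rule()]s.
#' @return A `digest_state`; attribute `"stage_dh"` records the DH after
#'   each stage.
#' @export
sequential_digest <- function(db, rules, seed = 1L, copies = 1L) {
  stopifnot(inherits(db, "protein_db"), length(rules) >= 1)
  total_bonds <- sum((nchar(db) - 1L) * copies)
  substrate_residues <- sum(nchar(db) * copies)
  with_seed(seed, {
    instances <- rep(unclass(db), each = copies)
    names(instances) <- NULL
    cleaved <- 0L
    stage_dh <- numeric(length(rules))
    for (i in seq_along(rules)) {
      res <- apply_rule_to_instances(instances, rules[[i]])
      instances <- res$instances
      cleaved <- cleaved + res$cleaved
      stage_dh[i] <- 100 * cleaved / total_bonds
    }
    state <- new_digest_state(instances, cleaved, total_bonds,
                              substrate_residues, seed)
    attr(state, "stage_dh") <- stage_dh
    state
  })
}

#' Ground-truth degree of hydrolysis
#'
#' Percentage of peptide bonds cleaved: `100 * cleaved / total`.
#'
#' @param state a `digest_state`.
#' @export
true_dh <- function(state) {
  stopifnot(inherits(state, "digest_state"))
  if (state$total_bonds <= 0) stop("total_bonds must be > 0")
  100 * state$cleaved_bonds / state$total_bonds
}

#' Average peptide mass
#'
#' Sum of average residue masses plus one water (18.02 Da). Average (not
#' monoisotopic) masses are used because ultrafiltration is a bulk-mass
#' process.
#'
#' @param sequence character vector of canonical AA sequences.
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence) {
  counts <- aa_count_matrix(sequence)
  drop(counts %*% AA_AVG_MASS[colnames(counts)]) + WATER_MASS
}

#' Ultrafiltration of a peptide pool into molecular-weight fractions
#'
#' Partitions the pool by average mass at the given cutoffs into fractions
#' `"<1 kDa"`, `"1-3 kDa"`, `"3-5 kDa"` and `"retentate"` (above the top
#' cutoff). Separation is imperfect in both directions, emulating a
#' sequential dead-end filtration train: with probability `leak_prob` a
#' portion `leak_frac` of an above-cutoff peptide passes into the adjacent
#' lower fraction, and with the same probability a portion of a
#' below-cutoff peptide is retained in the adjacent higher fraction (which
#' is why short peptides show up in the nominally high-MW fractions).
#' Total molar amount is conserved.
#'
#' @param state a `digest_state` (or a pool data.frame with columns
#'   `sequence`, `amount`).
#' @param cutoffs_kda ascending membrane cutoffs (kDa).
#' @param leak_prob per-peptide probability of imperfect separation.
#' @param leak_frac portion of the amount that crosses a membrane the
#'   wrong way.
#' @param seed RNG seed.
#' @return Named list of pools (data.frames `sequence`, `amount`), one per
#'   fraction label plus `"retentate"`.
#' @export
ultrafilter <- function(state, cutoffs_kda = c(1, 3, 5), leak_prob = 0.2,
                        leak_frac = 0.2, seed = 1L) {
  pool <- if (inherits(state, "digest_state")) state$pool else state
  if (is.unsorted(cutoffs_kda, strictly = TRUE)) {
    stop("cutoffs must be strictly ascending")
  }
  mass <- peptide_mass(pool$sequence)
  breaks <- c(0, cutoffs_kda * 1000, Inf)
  nf <- length(cutoffs_kda) + 1L
  bin <- findInterval(mass, breaks, left.open = TRUE)
  labels <- c(
    sprintf("<%g kDa", cutoffs_kda[1]),
    if (length(cutoffs_kda) > 1) {
      sprintf("%g-%g kDa", cutoffs_kda[-length(cutoffs_kda)],
              cutoffs_kda[-1])
    },
    "retentate"
  )
  n <- nrow(pool)
  amounts <- matrix(0, nrow = n, ncol = nf,
                    dimnames = list(NULL, labels))
  amounts[cbind(seq_len(n), bin)] <- pool$amount
  with_seed(seed, {
    # large -> small leakage (membrane lets some above-cutoff material pass)
    down <- bin > 1L & stats::runif(n) < leak_prob
    if (any(down)) {
      moved <- amounts[cbind(which(down), bin[down])] * leak_frac
      amounts[cbind(which(down), bin[down])] <-
        amounts[cbind(which(down), bin[down])] - moved
      amounts[cbind(which(down), bin[down] - 1L)] <-
        amounts[cbind(which(down), bin[down] - 1L)] + moved
    }
    # small -> large retention (membrane incompletely passes small material)
    up <- bin < nf & stats::runif(n) < leak_prob
    if (any(up)) {
      moved <- amounts[cbind(which(up), bin[up])] * leak_frac
      amounts[cbind(which(up), bin[up])] <-
        amounts[cbind(which(up), bin[up])] - moved
      amounts[cbind(which(up), bin[up] + 1L)] <-
        amounts[cbind(which(up), bin[up] + 1L)] + moved
    }
  })
  out <- lapply(seq_len(nf), function(j) {
    keep <- amounts[, j] > 0
    data.frame(sequence = pool$sequence[keep],
               amount = amounts[keep, j],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(out) <- labels
  out
}

default_detect_curve <- function() {
  # detection probability vs length: 0 below 3, ramp 0.3 -> 0.9 over 3-7,
  # plateau 0.9 to length 40, linear decline to 0.5 at 65, 0 above
  function(len) {
    p <- numeric(length(len))
    ramp <- len >= 3 & len < 7
    p[ramp] <- 0.3 + (0.9 - 0.3) * (len[ramp] - 3) / 4
    p[len >= 7 & len <= 40] <- 0.9
    tail <- len > 40 & len <= 65
    p[tail] <- 0.9 - (0.9 - 0.5) * (len[tail] - 40) / 25
    p
  }
}

#' MS observation model parameters
#'
#' @param detect_min_len,detect_max_len observable peptide length range
#'   (residues); shorter species (free AAs, dipeptides) are never seen.
#' @param lys_intensity_boost multiplicative intensity factor for
#'   Lys-containing peptides (>= 1); emulates the ionization advantage of
#'   alkaline residues.
#' @param length_detect_curve function length -> detection probability.
#' @param noise_cv lognormal sigma of multiplicative intensity noise.
#' @return Object of class `observation_params`.
#' @export
observation_params <- function(detect_min_len = 3L, detect_max_len = 65L,
                               lys_intensity_boost = 1.5,
                               length_detect_curve = default_detect_curve(),
                               noise_cv = 0.3) {
  stopifnot(lys_intensity_boost >= 1, noise_cv >= 0)
  structure(list(detect_min_len = detect_min_len,
                 detect_max_len = detect_max_len,
                 lys_intensity_boost = lys_intensity_boost,
                 length_detect_curve = length_detect_curve,
                 noise_cv = noise_cv),
            class = "observation_params")
}

#' Simulate MS observation of a peptide pool
#'
#' Bottom-up LC-MS/MS observation with its endogenous biases: peptides
#' outside the observable length range are never seen; detection is
#' Bernoulli per the length-detection curve; observed intensity is the
#' molar amount times a Lys boost (for Lys-containing peptides) times
#' lognormal noise.
#'
#' @param pool data.frame with `sequence`, `amount` (one fraction's pool).
#' @param params an [observation_params()].
#' @param sample_id sample id for the resulting table column.
#' @param seed RNG seed.
#' @return A single-sample [peptide_table()].
#' @export
ms_observe <- function(pool, params = observation_params(),
                       sample_id = "sample_1", seed = 1L) {
  stopifnot(inherits(params, "observation_params"))
  len <- nchar(pool$sequence)
  eligible <- len >= params$detect_min_len & len <= params$detect_max_len
  pool <- pool[eligible, , drop = FALSE]
  len <- len[eligible]
  with_seed(seed, {
    p <- params$length_detect_curve(len)
    detected <- stats::runif(nrow(pool)) < p
    pool <- pool[detected, , drop = FALSE]
    has_k <- grepl("K", pool$sequence, fixed = TRUE)
    noise <- if (params$noise_cv > 0) {
      exp(stats::rnorm(nrow(pool), 0, params$noise_cv))
    } else {
      rep(1, nrow(pool))
    }
    intensity <- pool$amount *
      ifelse(has_k, params$lys_intensity_boost, 1) * noise
    peptide_table(
      sequence = pool$sequence,
      intensity = matrix(intensity, ncol = 1,
                         dimnames = list(NULL, sample_id))
    )
  })
}

#' Score-generator parameters
#'
#' FRS/CHE scores are drawn from Beta distributions whose mean increases
#' with the peptide's aromatic+His residue fraction and decreases with
#' length, reflecting the association of short, aromatic-rich peptides with
#' antioxidant activity. Means are mapped through a logistic link.
#'
#' @param frs_base,che_base mean score of a reference 5-mer with no
#'   aromatic residues.
#' @param arom_coef logit-scale coefficient of the aromatic+His fraction.
#' @param frs_len_coef,che_len_coef logit-scale decrease per residue above
#'   length 5.
#' @param frs_phi,che_phi Beta precision (larger = tighter).
#' @param scorable_range predictor length range.
#' @export
score_params <- function(frs_base = 0.38, che_base = 0.20,
                         arom_coef = 1.2,
                         frs_len_coef = 0.03, che_len_coef = 0.045,
                         frs_phi = 18, che_phi = 30,
                         scorable_range = c(3L, 30L)) {
  structure(list(frs_base = frs_base, che_base = che_base,
                 arom_coef = arom_coef, frs_len_coef = frs_len_coef,
                 che_len_coef = che_len_coef, frs_phi = frs_phi,
                 che_phi = che_phi, scorable_range = scorable_range),
            class = "score_params")
}

#' Generate synthetic antioxidant scores
#'
#' Stand-in for an external sequence-based predictor: only peptides within
#' the scorable length range are scored; same seed, same table.
#'
#' @param peptides character vector of peptide sequences (duplicates
#'   ignored).
#' @param params a [score_params()].
#' @param seed RNG seed.
#' @return A [score_table()].
#' @export
synth_scores <- function(peptides, params = score_params(), seed = 1L) {
  peptides <- unique(peptides)
  len <- nchar(peptides)
  rng <- params$scorable_range
  peptides <- peptides[len >= rng[1] & len <= rng[2]]
  len <- nchar(peptides)
  counts <- aa_count_matrix(peptides)
  arom <- rowSums(counts[, c("F", "W", "Y", "H"), drop = FALSE]) / len
  draw <- function(base, len_coef, phi) {
    mu <- stats::plogis(stats::qlogis(base) + params$arom_coef * arom -
                          len_coef * (len - 5))
    stats::rbeta(length(mu), mu * phi, (1 - mu) * phi)
  }
  with_seed(seed, {
    frs <- draw(params$frs_base, params$frs_len_coef, params$frs_phi)
    che <- draw(params$che_base, params$che_len_coef, params$che_phi)
    score_table(peptides, pmin(pmax(frs, 0), 1), pmin(pmax(che, 0), 1),
                scorable_range = rng)
  })
}

#' Generate a synthetic sorption isotherm
#'
#' Langmuir-shaped equilibrium responses with multiplicative lognormal
#' noise. The default design is the 7-concentration series 0.25-10 mM Eq
#' Gly with duplicates of the 1st, 4th and 7th concentrations (10 points).
#'
#' @param kd,rmax generating parameters (> 0).
#' @param concentrations concentration series (mM Eq Gly).
#' @param noise_cv lognormal sigma of multiplicative response noise.
#' @param seed RNG seed.
#' @param duplicate_idx indices of concentrations measured in duplicate.
#' @param sample_id label.
#' @return An [isotherm()].
#' @export
synth_isotherm <- function(kd, rmax,
                           concentrations = c(0.25, 0.5, 1, 2, 4, 8, 10),
                           noise_cv = 0, seed = 1L,
                           duplicate_idx = c(1L, 4L, 7L),
                           sample_id = "") {
  stopifnot(kd > 0, rmax > 0)
  dup <- duplicate_idx[duplicate_idx <= length(concentrations)]
  conc <- sort(c(concentrations, concentrations[dup]))
  mu <- langmuir_response(conc, rmax, kd)
  with_seed(seed, {
    noise <- if (noise_cv > 0) exp(stats::rnorm(length(conc), 0, noise_cv))
             else rep(1, length(conc))
    isotherm(conc, mu * noise, sample_id)
  })
}

#' Generate a synthetic OPA plate
#'
#' Inverts the serine-equivalent/DH calculus: a sample with the given true
#' DH and protein content produces per-well absorbances `blank + intercept
#' + slope * serine_eq / df`, times multiplicative noise, at each dilution
#' factor in duplicate.
#'
#' @param true_dh true degree of hydrolysis (%, in (0, 100]).
#' @param protein_pct protein content of the assayed solution (% w/v).
#' @param curve a serine [calibration_curve()].
#' @param dfs dilution factors.
#' @param noise_cv lognormal sigma of multiplicative absorbance noise.
#' @param seed RNG seed.
#' @param sample_id sample label.
#' @param blank_absorbance blank absorbance.
#' @param n_replicates wells per dilution factor.
#' @return An [opa_plate()].
#' @export
synth_opa_plate <- function(true_dh, protein_pct, curve,
                            dfs = c(1, 2, 4, 8), noise_cv = 0, seed = 1L,
                            sample_id = "sample_1",
                            blank_absorbance = 0.05, n_replicates = 2L) {
  stopifnot(true_dh > 0, true_dh <= 100,
            inherits(curve, "calibration_curve"))
  serine_eq <- true_dh * protein_pct * 10 / 100
  df_col <- rep(dfs, each = n_replicates)
  rep_col <- rep(seq_len(n_replicates), times = length(dfs))
  mu <- blank_absorbance + curve$intercept + curve$slope * serine_eq / df_col
  with_seed(seed, {
    noise <- if (noise_cv > 0) exp(stats::rnorm(length(mu), 0, noise_cv))
             else rep(1, length(mu))
    opa_plate(rep(sample_id, length(mu)), df_col, rep_col, mu * noise,
              blank_absorbance)
  })
}

#' Mixture affinity model for synthetic isotherms
#'
#' Maps a fraction's peptide pool to a ground-truth dissociation constant
#' for Ni(II) binding: affinity per glycine equivalent weakens
#' exponentially with the pool's amount-weighted mean peptide length
#' (`kd = kd_ref * exp(slope * (wlen - len_ref))`, capped at `kd_max`).
#' Free amino acids and dipeptides (length < `min_len`) are excluded from
#' the mean: they lack the multidentate geometry that drives mixture-level
#' Ni(II) sorption. Defaults place a short-peptide pool (mean ~5 residues)
#' near 0.7 mM Eq Gly and a long-peptide pool (mean ~10) near 10 mM, the
#' span typical of hydrolysate mixtures on an NTA-Ni surface.
#'
#' @param pool data.frame `sequence`, `amount`.
#' @param kd_ref K_D (mM Eq Gly) at the reference mean length.
#' @param len_ref reference amount-weighted mean length (residues).
#' @param slope exponential rate per residue.
#' @param min_len minimum chain length entering the weighted mean.
#' @param kd_max cap on the generated K_D (mM Eq Gly).
#' @return Scalar true K_D (mM Eq Gly).
#' @export
pool_affinity_kd <- function(pool, kd_ref = 0.72, len_ref = 4.8,
                             slope = 0.54, min_len = 3L, kd_max = 20) {
  len <- nchar(pool$sequence)
  keep <- len >= min_len
  if (!any(keep)) return(kd_max)
  wlen <- sum(pool$amount[keep] * len[keep]) / sum(pool$amount[keep])
  min(kd_ref * exp(slope * (wlen - len_ref)), kd_max)
}

# Total residue units in a pool (mass-balance bookkeeping).
pool_residues <- function(pool) sum(pool$amount * nchar(pool$sequence))
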