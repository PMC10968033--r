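# End-to-end study orchestration: simulate (or load) a hydrolysate study,
# filter, summarize, aggregate scores, decompose overlap, fit isotherms,
# and emit reproducible report tables.

#' Combine single-sample peptide tables into one multi-sample table
#'
#' Rows are the union of sequences; a peptide absent from a sample gets
#' intensity 0 there.
#'
#' @param tables named list of [peptide_table()]s (names become sample ids
#'   when tables are single-sample with default ids).
#' @return A [peptide_table()].
#' @export
combine_peptide_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  tables <- lapply(tables, collapse_sequences)
  all_seq <- unique(unlist(lapply(tables, `[[`, "sequence")))
  samples <- unlist(lapply(tables, `[[`, "samples"))
  if (anyDuplicated(samples)) stop("sample ids collide across tables")
  intensity <- matrix(0, nrow = length(all_seq), ncol = length(samples),
                      dimnames = list(NULL, samples))
  for (tb in tables) {
    idx <- match(tb$sequence, all_seq)
    intensity[idx, tb$samples] <- tb$intensity
  }
  peptide_table(sequence = all_seq, intensity = intensity)
}

#' Default synthetic-study configuration
#'
#' One alcalase->flavourzyme chain ("AF") and one trypsin->flavourzyme
#' chain ("TF"), each ultrafiltered at 1/3/5 kDa, with the seven reported
#' fractions (the TF <1 kDa fraction is dropped, mirroring a failed
#' freeze-drying of that sample in the study design this emulates).
#' Substrate scale is chosen for desk-scale runtimes; all knobs are plain
#' list entries and can be overridden.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return A nested list (class `study_config`).
#' @export
default_study_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulation = list(n_proteins = 12L, mean_length = 300, length_sd = 30,
                      copies = 10L),
    chains = list(
      AF = list(enzymes = c("alcalase", "flavourzyme"),
                fractions = c(AF1 = "<1 kDa", AF13 = "1-3 kDa",
                              AF35 = "3-5 kDa", AFPPH = "PPH")),
      TF = list(enzymes = c("trypsin", "flavourzyme"),
                fractions = c(TF13 = "1-3 kDa", TF35 = "3-5 kDa",
                              TFPPH = "PPH"))
    ),
    ultrafilter = list(cutoffs_kda = c(1, 3, 5), leak_prob = 0.2,
                       leak_frac = 0.2),
    observation = list(lys_intensity_boost = 1.5, noise_cv = 0.3),
    scores = list(),
    thresholds = list(frs_threshold = 0.43, che_threshold = 0.30),
    spr = list(concentrations = c(0.25, 0.5, 1, 2, 4, 8, 10),
               duplicate_idx = c(1L, 4L, 7L), rmax = 100,
               noise_cv = 0.05,
               affinity = list(kd_ref = 0.72, len_ref = 4.8, slope = 0.54)),
    opa = list(slope = 1.2, intercept = 0.02, blank = 0.05,
               protein_pct = 0.2, dfs = c(1, 2, 4, 8), noise_cv = 0.01,
               cal_concentrations = 0.5 / 2^(0:7))
  ), class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Entries present in the file override the defaults of
#' [default_study_config()] (shallow per top-level section).
#'
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_study_config(seed = user$seed %||% 1L)
  for (key in setdiff(names(user), "seed")) {
    if (is.list(config[[key]]) && is.list(user[[key]])) {
      config[[key]][names(user[[key]])] <- user[[key]]
    } else {
      config[[key]] <- user[[key]]
    }
  }
  config
}

resolve_rule <- function(name) {
  switch(name,
         alcalase = rule_alcalase(),
         trypsin = rule_trypsin(),
         flavourzyme = rule_flavourzyme(),
         stop(sprintf("unknown enzyme '%s'", name)))
}

#' Run a complete synthetic screening study
#'
#' Generates a substrate database, digests it through each configured
#' enzyme chain, ultrafilters, observes each fraction by simulated MS,
#' filters and summarizes the peptide tables, attaches and aggregates
#' synthetic antioxidant scores, decomposes cross-fraction overlap, and
#' fits a 1:1 binding model to a synthetic isotherm of every fraction.
#' Identical config and seed give identical reports.
#'
#' @param config a `study_config` (see [default_study_config()]).
#' @param outdir optional output directory; when given, report tables are
#'   written as TSV plus one machine-readable JSON.
#' @return Object of class `study_report`: list with `hydrolysis` (Table
#'   1-analog), `summary` (Table 2-analog), `score_aggregation` and
#'   `overlap` (Figure 1-analog), `binding` (Table 3-analog), `ground_truth`
#'   and `config`.
#' @export
run_study <- function(config = default_study_config(), outdir = NULL) {
  seed <- config$seed
  sim <- config$simulation
  db <- make_protein_db(sim$n_proteins, sim$mean_length, sim$length_sd,
                        seed = seed + 101L)

  serine_cal <- calibration_curve(config$opa$slope, config$opa$intercept,
                                  analyte = "serine")
  cal_abs <- config$opa$intercept +
    config$opa$slope * config$opa$cal_concentrations
  serine_cal$abs_range <- range(cal_abs)

  pools <- list()
  truth <- list(fractions = list(), chains = list())
  hydrolysis_rows <- list()
  chain_i <- 0L
  for (chain_name in names(config$chains)) {
    chain_i <- chain_i + 1L
    chain <- config$chains[[chain_name]]
    rules <- lapply(chain$enzymes, resolve_rule)
    state <- sequential_digest(db, rules, seed = seed + 200L + chain_i,
                               copies = sim$copies)
    stage_dh <- attr(state, "stage_dh")
    fracs <- ultrafilter(state, config$ultrafilter$cutoffs_kda,
                         config$ultrafilter$leak_prob,
                         config$ultrafilter$leak_frac,
                         seed = seed + 300L + chain_i)
    fracs$PPH <- state$pool
    for (label in names(chain$fractions)) {
      pools[[label]] <- fracs[[chain$fractions[[label]]]]
    }
    # OPA plate measured DH vs ground truth
    plate <- synth_opa_plate(true_dh(state), config$opa$protein_pct,
                             serine_cal, dfs = config$opa$dfs,
                             noise_cv = config$opa$noise_cv,
                             seed = seed + 400L + chain_i,
                             sample_id = chain_name,
                             blank_absorbance = config$opa$blank)
    dh_meas <- dh_from_plate(plate, serine_cal,
                             stats::setNames(config$opa$protein_pct,
                                             chain_name))
    hydrolysis_rows[[chain_name]] <- data.frame(
      chain = chain_name,
      enzymes = paste(chain$enzymes, collapse = "+"),
      dh_true_stage1 = stage_dh[1],
      dh_true_final = true_dh(state),
      dh_opa = dh_meas$dh, dh_opa_sd = dh_meas$sd,
      stringsAsFactors = FALSE)
    truth$chains[[chain_name]] <- list(stage_dh = stage_dh,
                                       dh = true_dh(state))
  }

  obs_params <- observation_params(
    lys_intensity_boost = config$observation$lys_intensity_boost,
    noise_cv = config$observation$noise_cv)
  tables <- lapply(seq_along(pools), function(i) {
    ms_observe(pools[[i]], obs_params, sample_id = names(pools)[i],
               seed = seed + 500L + i)
  })
  names(tables) <- names(pools)
  tables <- lapply(tables, filter_peptides)
  combined <- filter_peptides(combine_peptide_tables(tables))

  scores <- do.call(score_params, config$scores)
  score_tab <- synth_scores(combined$sequence, scores, seed = seed + 600L)
  thresholds <- threshold_config(config$thresholds$frs_threshold,
                                 config$thresholds$che_threshold)

  # per-fraction statistics run on each fraction's own single-sample table:
  # in the combined table an intensity of zero cannot be told apart from
  # "not identified in this sample"
  summary_cols <- lapply(names(tables), function(s) {
    summary_table(tables[[s]], samples = s)
  })
  summary_tab <- Reduce(function(a, b) merge(a, b, by = "statistic",
                                             sort = FALSE),
                        summary_cols)
  agg_rows <- list()
  for (s in names(tables)) {
    scored_s <- attach_scores(tables[[s]], score_tab)
    for (prop in c("FRS", "CHE")) {
      a <- aggregate_scores(scored_s, s, prop, thresholds)
      agg_rows[[paste(s, prop)]] <- data.frame(
        sample = s, property = prop, threshold = a$threshold,
        n_scored = a$n_scored, n_above = a$n_above,
        frac_ids_above = a$frac_ids_above,
        intensity_frac_above = a$intensity_frac_above,
        intensity_frac_above_raw = a$intensity_frac_above_raw,
        mean_score = a$mean_score, stringsAsFactors = FALSE)
    }
  }
  scored <- attach_scores(combined, score_tab)
  sets <- lapply(names(tables), function(s) tables[[s]]$sequence)
  names(sets) <- names(tables)
  overlap <- overlap_analysis(sets)

  binding_rows <- list()
  for (i in seq_along(pools)) {
    label <- names(pools)[i]
    kd_true <- pool_affinity_kd(pools[[i]],
                                config$spr$affinity$kd_ref,
                                config$spr$affinity$len_ref,
                                config$spr$affinity$slope)
    iso <- synth_isotherm(kd_true, config$spr$rmax,
                          config$spr$concentrations,
                          noise_cv = config$spr$noise_cv,
                          seed = seed + 700L + i,
                          duplicate_idx = config$spr$duplicate_idx,
                          sample_id = label)
    fit <- saturation_check(fit_langmuir(iso))
    mn_mass <- sum(pools[[i]]$amount * peptide_mass(pools[[i]]$sequence)) /
      sum(pools[[i]]$amount)
    binding_rows[[label]] <- data.frame(
      sample = label,
      conc_mm_eq_gly = 1000 / mn_mass,  # 1 mg/mL on a number-average basis
      kd = fit$kd, se_kd = fit$se_kd, rmax = fit$rmax,
      kd_true = kd_true,
      saturation_flag = fit$saturation_flag, stringsAsFactors = FALSE)
    truth$fractions[[label]] <- list(kd_true = kd_true,
                                     n_distinct = nrow(pools[[i]]))
  }

  report <- structure(list(
    hydrolysis = do.call(rbind, c(hydrolysis_rows,
                                  make.row.names = FALSE)),
    summary = summary_tab,
    score_aggregation = do.call(rbind, c(agg_rows,
                                         make.row.names = FALSE)),
    overlap = overlap,
    binding = do.call(rbind, c(binding_rows, make.row.names = FALSE)),
    score_coverage = attr(scored, "score_coverage"),
    filter_report = filter_report(combined),
    ground_truth = truth,
    seed = seed
  ), class = "study_report")

  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d; %d fractions\n", x$seed,
              nrow(x$binding)))
  cat("  hydrolysis (DH%):\n")
  print(x$hydrolysis, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' TSV per table plus one machine-readable `report.json` holding every
#' number (byte-identical across reruns with the same config and seed).
#'
#' @param report a `study_report`.
#' @param outdir output directory (created if needed).
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$hydrolysis,
                     file.path(outdir, "table1_hydrolysis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary,
                     file.path(outdir, "table2_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$score_aggregation,
                     file.path(outdir, "figure1_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$overlap$patterns,
                     file.path(outdir, "figure1_upset.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)
  utils::write.table(report$binding,
                     file.path(outdir, "table3_binding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    seed = report$seed,
    hydrolysis = report$hydrolysis,
    summary = report$summary,
    score_aggregation = report$score_aggregation,
    upset = report$overlap$patterns,
    conserved = report$overlap$conserved,
    unique_counts = as.list(report$overlap$unique_counts),
    binding = report$binding,
    ground_truth = report$ground_truth
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Reference fraction summary statistics
#'
#' Published summary statistics for seven ultrafiltration fractions of
#' sequentially digested potato protein hydrolysates (alcalase- and
#' trypsin-initiated chains): peptide ID counts, arithmetic and
#' intensity-weighted mean length and charge, and relative molar AA
#' abundance (percent). Shipped as a plain-text fixture; used to check the
#' internal consistency of the additive charge model against the
#' residue-pool composition.
#'
#' @return Data.frame: one row per statistic, one column per fraction.
#' @export
load_reference_summary <- function() {
  path <- system.file("extdata", "fraction_summary_reference.tsv",
                      package = "hydroscreen", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}

#' Reconstruct weighted-mean charge from composition
#'
#' The charge-linearity identity: under the additive per-residue charge
#' model and the residue-pool definition of molar AA abundance, the
#' intensity-weighted mean peptide charge equals the weighted mean length
#' times the per-residue net charge of the pool. This reconstructs the
#' former from a fraction's printed summary column.
#'
#' @param weighted_mean_length intensity-weighted mean peptide length.
#' @param aa_percent named vector of relative molar AA abundances in
#'   percent, named by 3-letter or 1-letter code.
#' @param model a [charge_model()].
#' @return Reconstructed weighted-mean net charge.
#' @export
reconstruct_weighted_charge <- function(weighted_mean_length, aa_percent,
                                        model = charge_model()) {
  three <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")
  nm <- names(aa_percent)
  nm <- ifelse(nm %in% names(three), three[nm], nm)
  if (!all(nm %in% AA_LETTERS)) stop("unrecognized amino-acid names")
  per_residue <- sum(unclass(model)[nm] * aa_percent / 100)
  weighted_mean_length * per_residue
}
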