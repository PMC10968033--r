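# Wet-assay calculus: OPA calibration, serine/glycine equivalents, degree
# of hydrolysis (DH%), and protein content/yield arithmetic.

#' Fit a linear calibration curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept`, as used for the 8-point L-serine (DH assay) and glycine
#' (peptide quantification) OPA calibrations.
#'
#' @param concentrations analyte concentrations (mg/mL for serine, mM for
#'   glycine); at least 3 distinct values.
#' @param absorbances measured absorbances (AU, 340 nm).
#' @param analyte `"serine"` or `"glycine"`.
#' @return Object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `analyte` and `abs_range` (observed calibrant absorbance
#'   range, used for in-range checks).
#' @export
fit_calibration <- function(concentrations, absorbances,
                            analyte = c("serine", "glycine")) {
  analyte <- match.arg(analyte)
  if (length(concentrations) < 3) stop("need at least 3 calibration points")
  if (length(concentrations) != length(absorbances)) {
    stop("concentrations and absorbances must have equal length")
  }
  if (stats::sd(concentrations) == 0) {
    stop("singular design: concentrations are all equal")
  }
  fit <- stats::lm(absorbances ~ concentrations)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbances - mean(absorbances))^2)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    analyte = analyte,
    abs_range = range(absorbances)
  ), class = "calibration_curve")
}

#' Construct a calibration curve from known coefficients
#' @inheritParams fit_calibration
#' @param slope,intercept line coefficients (slope > 0).
#' @param abs_range absorbance range considered in-calibration.
#' @export
calibration_curve <- function(slope, intercept,
                              analyte = c("serine", "glycine"),
                              abs_range = c(-Inf, Inf)) {
  analyte <- match.arg(analyte)
  if (slope <= 0) stop("calibration slope must be > 0")
  structure(list(slope = slope, intercept = intercept, r_squared = NA_real_,
                 analyte = analyte, abs_range = abs_range),
            class = "calibration_curve")
}

#' Serine equivalents from OPA absorbance
#'
#' `((abs_sample - abs_blank - intercept) / slope) * df`, in mg Ser/mL of
#' the undiluted sample. Negative results signal absorbance below the
#' blank/calibration floor and raise an error rather than being clipped.
#'
#' @param abs_sample,abs_blank absorbances (AU).
#' @param curve a serine [calibration_curve()].
#' @param df dilution factor (positive integer).
#' @return mg serine equivalents per mL.
#' @export
serine_equivalents <- function(abs_sample, abs_blank, curve, df = 1L) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0")
  if (any(df < 1)) stop("dilution factor must be >= 1")
  out <- ((abs_sample - abs_blank - curve$intercept) / curve$slope) * df
  if (any(out < 0)) {
    stop("absorbance below blank/calibration floor (negative concentration)")
  }
  out
}

#' Degree of hydrolysis from serine equivalents
#'
#' `DH% = serine_eq / (protein_pct * 10) * 100`; the factor 10 converts a
#' protein content in % w/v to mg/mL.
#'
#' @param serine_eq mg Ser/mL (undiluted basis).
#' @param protein_pct protein content of the assayed dilution, % w/v
#'   (must be > 0).
#' @return DH in percent.
#' @export
dh_percent <- function(serine_eq, protein_pct) {
  if (any(protein_pct <= 0)) stop("protein_pct must be > 0")
  serine_eq / (protein_pct * 10) * 100
}

#' Construct an OPA microplate
#'
#' @param sample character sample ids per well.
#' @param df dilution factor per well (>= 1).
#' @param replicate replicate index per well.
#' @param absorbance absorbance at 340 nm per well.
#' @param blank_absorbance scalar blank (reagent + water) absorbance.
#' @return Data.frame of class `opa_plate` with the blank as an attribute.
#' @export
opa_plate <- function(sample, df, replicate, absorbance, blank_absorbance) {
  if (any(df < 1)) stop("dilution factors must be >= 1")
  wells <- data.frame(sample = as.character(sample), df = as.numeric(df),
                      replicate = as.integer(replicate),
                      absorbance = as.numeric(absorbance),
                      stringsAsFactors = FALSE)
  key <- paste(wells$sample, wells$df, wells$replicate)
  if (anyDuplicated(key)) {
    stop("replicate indices must be unique per (sample, df)")
  }
  structure(wells, class = c("opa_plate", "data.frame"),
            blank_absorbance = blank_absorbance)
}

#' Read an OPA plate CSV
#'
#' Expects columns `sample, df, replicate, absorbance`. Rows with sample id
#' `"blank"` (case-insensitive) are averaged into the blank absorbance.
#'
#' @param path CSV path.
#' @param blank_absorbance blank absorbance; if `NULL`, taken from blank
#'   rows.
#' @export
read_opa_plate <- function(path, blank_absorbance = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample", "df", "replicate", "absorbance")) {
    if (!col %in% names(df)) {
      stop(sprintf("format error: missing column '%s'", col))
    }
  }
  is_blank <- tolower(df$sample) == "blank"
  if (is.null(blank_absorbance)) {
    if (!any(is_blank)) stop("no blank rows and no blank_absorbance given")
    blank_absorbance <- mean(df$absorbance[is_blank])
  }
  df <- df[!is_blank, , drop = FALSE]
  opa_plate(df$sample, df$df, df$replicate, df$absorbance, blank_absorbance)
}

#' Degree of hydrolysis from an OPA plate
#'
#' Converts each in-range well to serine equivalents and DH%, then averages
#' per sample (unweighted mean +/- sd). Wells whose blank-corrected
#' absorbance falls outside the calibrant absorbance range (e.g. saturated
#' wells at low dilution) are excluded and reported.
#'
#' @param plate an [opa_plate()].
#' @param curve a serine [calibration_curve()] with a finite `abs_range`.
#' @param protein_pct_by_sample named numeric vector/list: protein content
#'   (% w/v) of each sample's undiluted assay solution.
#' @return Data.frame (class `dh_result`) with columns `sample`, `dh`, `sd`,
#'   `n_wells`, `n_excluded`.
#' @export
dh_from_plate <- function(plate, curve, protein_pct_by_sample) {
  stopifnot(inherits(plate, "opa_plate"),
            inherits(curve, "calibration_curve"))
  blank <- attr(plate, "blank_absorbance")
  protein_pct_by_sample <- unlist(protein_pct_by_sample)
  samples <- unique(plate$sample)
  missing <- setdiff(samples, names(protein_pct_by_sample))
  if (length(missing)) {
    stop(sprintf("no protein content for sample(s): %s",
                 paste(missing, collapse = ", ")))
  }
  rows <- lapply(samples, function(s) {
    wells <- plate[plate$sample == s, , drop = FALSE]
    corrected <- wells$absorbance - blank
    in_range <- corrected >= curve$abs_range[1] &
      corrected <= curve$abs_range[2]
    if (!any(in_range)) {
      stop(sprintf("no wells within calibration range for sample '%s'", s))
    }
    wells <- wells[in_range, , drop = FALSE]
    ser <- serine_equivalents(wells$absorbance, blank, curve, wells$df)
    dh <- dh_percent(ser, protein_pct_by_sample[[s]])
    data.frame(sample = s, dh = mean(dh),
               sd = if (length(dh) > 1) stats::sd(dh) else 0,
               n_wells = length(dh), n_excluded = sum(!in_range),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dh_result", "data.frame"))
}

#' Protein content and yield of a hydrolysis supernatant
#'
#' `protein_g = dumas_pct / 100 * supernatant_g`;
#' `yield_pct = protein_g / substrate_g * 100`. With
#' `protein_basis = TRUE` the divisor becomes `substrate_g * purity`,
#' expressing yield on the substrate's protein basis instead of raw mass.
#'
#' @param dumas_pct protein content of the supernatant (%, nitrogen x 6.25).
#' @param supernatant_g supernatant mass (g, > 0).
#' @param substrate_g starting protein-concentrate mass (g, > 0).
#' @param protein_basis divide by `substrate_g * purity`.
#' @param purity substrate protein purity (fraction), default 0.84.
#' @return List with `protein_g` and `yield_pct`.
#' @export
protein_and_yield <- function(dumas_pct, supernatant_g, substrate_g,
                              protein_basis = FALSE, purity = 0.84) {
  if (any(c(supernatant_g, substrate_g) <= 0)) {
    stop("masses must be > 0")
  }
  protein_g <- dumas_pct / 100 * supernatant_g
  divisor <- if (protein_basis) substrate_g * purity else substrate_g
  list(protein_g = protein_g, yield_pct = protein_g / divisor * 100)
}

#' Glycine equivalents from OPA absorbance
#'
#' `(abs_sample - abs_blank - intercept) / slope`, in mM Eq Gly (no
#' dilution factor: the peptide-quantification protocol assays undiluted
#' 1 mg/mL solutions).
#'
#' @param abs_sample,abs_blank absorbances (AU).
#' @param curve a glycine [calibration_curve()].
#' @return mM glycine equivalents.
#' @export
glycine_equivalents <- function(abs_sample, abs_blank, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0) stop("calibration slope must be > 0")
  out <- (abs_sample - abs_blank - curve$intercept) / curve$slope
  if (any(out < 0)) {
    stop("absorbance below blank/calibration floor (negative concentration)")
  }
  out
}
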