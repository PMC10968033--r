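---
title: "hydroscreen: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hydroscreen: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydroscreen)
```

`hydroscreen` turns the screening workflow for antioxidant protein
hydrolysates — peptidomic summary statistics, activity-score aggregation,
hydrolysis-assay calculus, and SPR binding analysis — into a tested pipeline,
with a synthetic-data module standing in for the wet lab. This vignette is
the package's own account of the science: what each model assumes, which
knobs matter, what the synthetic world does and does not emulate, and where
the design was genuinely open.

## 1. Intensity-weighted peptidomic statistics

A label-free bottom-up experiment yields, per sample, peptide sequences and
MS intensities. Intensity is treated as proportional to molar abundance
within a sample, giving relative weights $w_i = I_i / \sum_j I_j$ over
quantified peptides. Identified-but-unquantified peptides (intensity 0) count
toward identification statistics (`n_peptide_ids`, arithmetic means) but
carry zero weight in abundance-based statistics — identification is evidence
of presence, intensity is the only quantitative signal.

**Charge.** Net peptide charge at neutral pH uses fixed additive per-residue
contributions: Asp, Glu −1; Arg, Lys +1; His +0.1; termini and all other
residues 0. This is a deliberate heuristic (His's fractional value reflects
its partial protonation near pH 7); no Henderson–Hasselbalch machinery is
offered in v1, because the screening decisions it supports only need
rank-level charge information.

**Molar AA abundance.** Two denominators are defensible for the
intensity-weighted residue composition: the mean of per-peptide compositions,
or the residue pool $p_{aa} = \sum_i w_i n_{i,aa} / \sum_i w_i L_i$. We use
the residue pool, for one decisive reason: it makes the *charge-linearity
identity* exact,
$$\bar{c}_w = \bar{L}_w \cdot \sum_{aa} \text{contrib}(aa)\, p_{aa},$$
so weighted mean charge, weighted mean length and composition form a
consistent triple. The identity is asserted to 1e-12 in the test suite, and
— applied to a published seven-fraction reference table shipped in
`inst/extdata/` — reconstructs each fraction's printed weighted-mean charge
within ±0.06 charge units from its printed length and composition alone (the
residual is consistent with the table's one-decimal rounding). That
reconstruction is the package's acceptance target.

**Length histogram.** Default intensity-weighted bins 3–5, 6–10, 11–20,
21–65 residues: the low bins resolve the range where hydrolysates
concentrate; binning is configurable since no standard exists.

## 2. Score aggregation

FRS (radical scavenging) and CHE (metal chelation) scores in $[0,1]$ are
*inputs*, produced by an external sequence-based predictor that accepts 3–30
residue peptides; the package never computes a score of its own. Thresholds
default to the predictor's operating points, FRS ≥ 0.43 and CHE ≥ 0.30,
compared inclusively.

The quantitative headline — "share of peptide-level intensity above
threshold" — has an ambiguous denominator when some peptides are unscored
(too long, or absent from the score table). Both conventions are therefore
emitted: `intensity_frac_above` renormalizes weights over scored+quantified
peptides; `intensity_frac_above_raw` divides by all quantified intensity.
The raw share is used for headline percentages (it answers "how much of what
we measured is predicted active"), and the unscored intensity share is
reported alongside so neither number hides coverage.

Overlap analysis uses UpSet semantics: each sequence in the union belongs to
exactly one membership pattern, so the $2^k - 1$ exclusive intersection
counts sum to the union size (a tested invariant). Duplicate rows (charge
states) are collapsed, summing intensities, before set analysis. ANOVA +
Tukey HSD for score-distribution comparison is textbook plumbing on
`stats::aov`.

## 3. Assay calculus

The OPA chemistry quantifies free α-amino groups; calibrated against
L-serine it yields serine equivalents
$\mathrm{Ser_{eq}} = ((A_s - A_b - \text{intercept})/\text{slope})\cdot DF$
and the degree of hydrolysis $DH\% = \mathrm{Ser_{eq}} / (P \cdot 10) \cdot
100$ with $P$ the protein content in % w/v (the factor 10 converts to
mg/mL). This operational DH is implemented verbatim; it is *not* the
classical $h/h_{tot}$ formulation (no α, β, $h_{tot}$ constants), and no
reconciliation is attempted. Choices worth noting:

* Negative concentrations raise errors instead of clipping to zero —
  silent clipping hides calibration drift.
* Wells are included only when blank-corrected absorbance falls inside the
  calibrant absorbance range; saturated low-dilution wells are excluded and
  counted. Replicate aggregation is an unweighted mean ± sd.
* Protein yield divides by the raw substrate mass as the workflow prints
  it; `protein_basis = TRUE` applies a purity divisor (default 0.84),
  exposing rather than resolving that ambiguity.
* Glycine equivalents (peptide concentration for SPR, mM Eq Gly) use the
  same inversion with DF = 1, matching the undiluted 1 mg/mL protocol.

## 4. SPR binding analysis

Equilibrium responses at increasing analyte concentration form a sorption
isotherm; the 1:1 Langmuir model $R(C) = R_{max} C / (K_D + C)$ is fitted by
unweighted nonlinear least squares on the linear response scale. Numerical
choices, declared rather than inferred from any upstream software:

* Initialization $R_{max}^0 = 1.1 \max R$, $K_D^0$ = concentration whose
  response is nearest $R_{max}^0/2$; Levenberg–Marquardt steps constrained
  to $K_D > 0$, $R_{max} \ge 0$; convergence when the relative parameter
  change falls below 1e-10, at most 500 iterations; non-convergence is an
  error with diagnostics, never a silent result.
* Standard errors come from the residual-variance-scaled inverse
  Gauss–Newton curvature. Duplicate concentrations (the default design
  duplicates the 1st, 4th and 7th of 0.25–10 mM Eq Gly) enter as
  independent residuals, preserving error degrees of freedom.
* A constant instrument offset is assumed already subtracted during isotherm
  construction; `fit_offset = TRUE` adds it as a third parameter for
  sensitivity analysis.
* The *saturation flag*: when $\hat{K}_D > C_{max}/2$ (strict inequality),
  the assayed range never approached saturation and the estimate is likely
  an underestimate of the true constant; the fit is annotated, not
  rejected. Simulations in the acceptance suite show that with a true
  $K_D = 8$ against $C_{max} = 10$ the flag fires in >90% of noisy
  replicates.

The fitter is validated three ways: noiseless recovery to 1e-6 relative
anywhere in $[0.1\,C_{min},\, 2\,C_{max}]$; agreement with an independent
log-grid-search oracle (closed-form conditional $R_{max}$) within grid
spacing under noise; and ≥85% empirical coverage of 95% Wald intervals over
500 noisy replicates. Kinetic ($k_{on}/k_{off}$), mass-transport and
competition models are out of scope; note that for complex mixtures SPR is
effectively a pseudo-competition assay, one reason mixture $K_D$s should be
read as ranges rather than constants.

## 5. The synthetic world

The generator produces every input the pipeline reads, with the statistical
structure the analysis assumes — so a green end-to-end test establishes that
the *pipeline* recovers the structure the *generator* put in, no more.

**Digestion** is a terminal-state bond-sampling model: each eligible bond
(P1 in the rule's residue set, optionally blocked by P1′ = Pro) is cleaved
independently with probability `p_cut`; an exopeptidase component then trims
N-terminal residues round by round, releasing free amino acids; each cut or
trim increments the cleaved-bond count, giving ground-truth
$DH = 100\,\text{cleaved}/\text{total}$. There is no kinetics, no enzyme
saturation, no site accessibility. Stock rules: trypsin (C-terminal K/R,
`p_cut = 1`, Pro block on), "alcalase" as a broad 10-residue P1 set at
`p_cut = 0.40`, "flavourzyme" as the same broad set at `p_cut = 0.12` plus
two trimming rounds at 0.32 — declared stand-ins, not claims about the real
enzymes, calibrated (together with a potato-like, acidic-rich substrate
composition) so the alcalase chain runs ≈21% → ≈37% DH across its two
stages, the published two-stage pattern. A known limitation of the iid bond
model: it cannot simultaneously reproduce the trypsin chain's published rise
(13% → 38%) with the same shared flavourzyme rule, because tryptic pools
offer the exo component fewer termini; the trypsin chain plateaus near 25%
here. Real digestion kinetics (site accessibility, enzyme saturation) break
the iid assumption in exactly the direction that closes this gap.

**Ultrafiltration** bins peptides by average mass (average, not
monoisotopic: membranes see bulk mass) at 1/3/5 kDa. Separation is
imperfect in *both* directions: with probability `leak_prob` a portion
`leak_frac` of an above-cutoff peptide passes into the adjacent lower
fraction, and likewise below-cutoff material is retained upward. The upward
retention is what seeds nominally high-MW fractions with abundant short
peptides — a feature real fraction data show prominently — and a sequential
dead-end filtration train produces it naturally; a strictly one-directional
(large→small) model cannot. Molar amount is conserved to 1e-9 (tested).

**MS observation** never sees peptides outside 3–65 residues (free AAs and
dipeptides are invisible to the workflow), detects by a length curve (ramp
0.3→0.9 over 3–7 residues, plateau to 40, declining to 0.5 at 65 — a
stand-in, fully configurable), multiplies Lys-containing peptides' intensity
by 1.5 (the ionization advantage of alkaline residues), and applies
lognormal noise (σ = 0.3). The Lys boost measurably inflates the observed
Lys molar abundance over the pool truth (tested over seeds).

**Scores** are Beta draws whose logit-mean rises with aromatic+His fraction
and falls with length (CHE: base 0.20 at 5 residues, precision 30; FRS:
base 0.38, precision 18). Parameters were chosen once so that arithmetic
mean CHE sits near 0.2 and short-peptide fractions put roughly 10–20% of
intensity above the 0.30 threshold versus a few percent for long-peptide
fractions — the magnitude pattern reported for real fractions.

**Affinity.** To give each synthetic fraction an isotherm, a mixture-level
true $K_D$ is derived from its pool: $K_D = 0.72\,e^{0.54(\bar{L}_w - 4.8)}$
mM Eq Gly on the amount-weighted mean length of chains ≥3 residues, capped
at 20. Anchors put a ~5-residue pool near 0.7 and a ~9.5-residue pool near
9 mM Eq Gly, the span reported for hydrolysate mixtures on NTA-Ni surfaces;
the exponential form encodes only "longer average chains bind weaker per
glycine equivalent", the cap keeps degenerate long-pool fractions physically
sane, and the length cut excludes species without multidentate geometry.
This is the single most *invented* component of the synthetic world: nothing
in it validates a real length–affinity law, it exists so the end-to-end
ordering test has a ground truth to recover.

**What a green test establishes.** The end-to-end acceptance criterion — in
≥80% of seeds the broad-enzyme <1 kDa fraction has shorter weighted mean
length, a higher CHE intensity share, and lower fitted $K_D$ than the
specific-enzyme 3–5 kDa fraction — demonstrates that the pipeline's
statistics recover a known generative ordering through digestion,
fractionation, biased observation, scoring and isotherm fitting. It does not
validate the score generator or the affinity law against nature.

## 6. Numerical and interface choices

* Filtering precedence: reverse first, then contaminants (only unambiguous
  ones — no target accession), then length; the report's counts are
  precedence-dependent by construction and sum to the input count.
* FDR is an upstream search setting; the reader records it as metadata and
  never re-derives it (decoy scores are not carried in peptide tables).
* Non-canonical residues (B, J, O, U, X, Z) are rejected at read time with
  row- or accession-level errors: downstream mass and charge models are
  defined on the 20 canonical letters only.
* All generators are pure functions of (parameters, seed) and restore the
  global RNG state; `run_study()` derives per-stage sub-seeds from one
  master seed, so identical config + seed gives byte-identical report JSON
  (tested).
* Degenerate inputs error loudly and early: all-zero intensity vectors, no
  scored peptides, all-saturated plates, all-nonpositive isotherms.
* The study default (12 proteins × 300 residues × 10 copies) is a
  desk-scale stand-in for a real database; peptide-ID counts per fraction
  (hundreds to thousands) are an order below real experiments, so per-seed
  variance of fraction statistics is correspondingly larger.

## 7. Known limitations

* Charge is a pH-7 heuristic; no pKa machinery, no termini.
* The trypsin-chain DH gap described in §5; Table-style DH values for
  specific enzymes should not be read quantitatively from the simulator.
* Ultrafiltration leakage probability is size-independent; real membranes
  retain small peptides with strongly size-dependent probability.
* The affinity law and score generator are screening stand-ins; only their
  orderings, not their magnitudes, are meaningful.
* The 1:1 model assumes one analyte class; mixture isotherms without a
  plateau (pseudo-competition) violate it by construction, which is exactly
  what the saturation flag is for.
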