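Package: hydroscreen
Title: Screening Protein Hydrolysates for Antioxidant Peptide Candidates
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative peptidomics-based screening of protein
    hydrolysates as metal-chelating and radical-scavenging antioxidant
    ingredients. Reads and filters MaxQuant-style peptide identification
    tables, computes intensity-weighted summary statistics (peptide length,
    additive net charge, relative molar amino-acid abundance), aggregates
    externally predicted free radical-scavenging (FRS) and metal-chelating
    (CHE) peptide scores against activity thresholds, implements the OPA
    assay calculus (serine/glycine equivalents, degree of hydrolysis) and
    protein yield arithmetic, and fits 1:1 Langmuir sorption isotherms from
    surface plasmon resonance equilibrium data to estimate dissociation
    constants with saturation-adequacy diagnostics. A synthetic-data module
    simulates sequential two-enzyme digestion with ground-truth degree of
    hydrolysis, ultrafiltration into molecular-weight fractions, biased
    mass-spectrometric observation, score tables, isotherms and OPA plates,
    so the full pipeline can be exercised and validated without wet-lab
    input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
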