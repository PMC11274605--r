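Package: pisar
Title: Proteome Integral Solubility Alteration (PISA) Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Proteome Integral Solubility Alteration
    (PISA) experiments that quantify drug-induced protein thermal stability
    shifts alongside global protein and transcript abundance. Implements a
    two-state sigmoid melting model with equal-volume solubility-integral
    pooling over a temperature gradient, a synthetic experiment generator
    with ground truth (correlated transcript and protein effects, melting
    midpoint shifts, methyl-peptide occupancy), TMT-style abundance table
    filtering and normalization, three differential layers (protein
    abundance, thermal stability via PISA-to-global normalization,
    transcripts with Benjamini-Hochberg control), lysine-methyl peptide
    site statistics with double normalization, chi-square gene-set
    enrichment with random-draw controls, and three-layer overlap
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
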