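Package: pairedscreen
Title: Paired Isogenic Cell-Line siRNA Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide RNAi viability screens run in
    paired isogenic cell lines (e.g. a patient-derived mutant line and its
    cDNA-corrected counterpart). Provides plate- and screen-effect
    normalization of log fluorescence intensities by an additive linear
    model, empirical-Bayes moderated t-tests for differential viability with
    Benjamini-Hochberg false-discovery-rate hit selection, scoring of
    single-siRNA deconvolution rescreens by differential ratio and toxicity
    with a gene-level confirmation rule, division-corrected drug-sensitivity
    comparison by exact Wilcoxon rank-sum tests, and a synthetic-screen
    generator with ground-truth manifests for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
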