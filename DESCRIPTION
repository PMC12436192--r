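Package: longewas
Title: Longitudinal Epigenome-Wide Association Analysis with Technical and
    Cell-Composition Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for epigenome-wide association studies
    (EWAS) of DNA methylation array data in a longitudinal case-control
    design: sample-level quality control (call rate, missing signal,
    sex concordance, control-probe outliers), probe filtering
    (SNP-proximal and cross-reactive probes), beta-to-M-value
    transformation, technical-variance adjustment via control-probe
    principal components, reference-based white-blood-cell deconvolution
    by constrained projection, and three association designs
    (case-control Welch test on adjusted M-values, logistic and
    continuous prediction of treatment response from baseline
    methylation, and within-patient longitudinal change stratified by
    responder status), plus a robust smoking EWAS, hypergeometric
    overlap tests, genomic-inflation and QQ diagnostics, and
    Manhattan-plot data export. Includes a fully synthetic EPIC-like
    data generator with known ground truth (cell mixtures, batch
    structure in control probes, sex-chromosome signal, spiked effects,
    and anxiety-score trajectories with a responder subpopulation) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    quadprog,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
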