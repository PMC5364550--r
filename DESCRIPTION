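Package: uta
Title: Single-Cell Analysis of miRNA-Mediated Repression from
    Dual-Fluorescence Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements the molecular-titration analysis of microRNA
    target repression at single-cell resolution. Provides the closed-form
    steady state of the two-species titration model and its dose-response
    and parameter-grid simulations, a synthetic generator of per-cell
    two-channel fluorescence event tables (heterogeneous transfection,
    measurement noise, autofluorescence), transfer-function construction
    from gated events, weighted nonlinear least-squares estimation of the
    effective miRNA abundance (theta) and dissociation (lambda)
    parameters, ordinal functional classification (low/mid/high) of
    repression curves, small-RNA count normalization (median-of-ratios,
    RPM/RPKM, compartment ratios) with Kruskal-Wallis/Dunn group
    comparison, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
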