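Package: protflow
Title: Quality Control and Preliminary Analysis Workflows for MS-Based
    Proteomics and Interactomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, scriptable workflows for routine quality control and
    preliminary analysis of mass-spectrometry proteomics data. Reads generic
    intensity or spectral-count matrices as well as FragPipe- and DIA-NN-style
    reports, removes common contaminants, and computes per-sample QC metrics
    (identification counts, missingness, coverage, shared identifications,
    coefficients of variation). The proteomics workflow chains consistency
    filtering, optional median or quantile normalization, left-censored
    (QRILC-style) imputation, PCA, hierarchical clustering, and Welch-test
    differential abundance with Benjamini-Hochberg correction and volcano
    classification. The interactomics workflow writes and reads SAINTexpress
    files, scores bait-prey pairs with CRAPome-style fold changes, filters
    high-confidence interactors, maps known interactions, computes
    MS-microscopy localization profiles and local hypergeometric enrichment,
    and exports networks as edge/node tables. Also included: total-ion
    chromatogram run-series metrics, colocalization maps from multi-channel
    z-stacks, a batch pipeline runner with success/failure markers, and
    deterministic synthetic-data generators with ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
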