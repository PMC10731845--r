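Package: metabomwas
Title: Metabolome-Wide Association Analysis for Untargeted LC-HRMS
    Case-Control Studies
Version: 0.1.0
Authors@R:
    person("PEG", "Metabolomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for metabolome-wide association studies
    (MWAS) of case-control cohorts profiled by untargeted liquid
    chromatography high-resolution mass spectrometry.  Provides feature-table
    preprocessing (cross-run alignment, replicate quality filters, quantile
    normalization, parametric empirical-Bayes batch correction, technical
    cluster detection), moderated-t differential abundance testing with
    per-wave logistic models pooled by fixed-effects meta-analysis, a
    replication rubric, adduct-based metabolite annotation, permutation-based
    weighted pathway enrichment, correlation networks of hits, and a
    cross-study external-validation meta-analysis combining fold changes and
    p-values from summary statistics.  A synthetic cohort generator with
    ground-truth labels supports power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
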