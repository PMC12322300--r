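Package: pairProteo
Title: Paired Tumor/Skin DIA Proteomics Analysis with GO-Level Mixed Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential protein abundance analysis for matched
    tumor/normal designs measured by data-independent acquisition (DIA)
    mass spectrometry, built around cutaneous neurofibroma versus
    overlying-skin comparisons. Provides confidence filtering of protein
    identifications, classification of missing values into
    below-limit-of-detection (informative) and missing-at-random cells
    with dataset-minimum imputation, Gene Ontology (GO) term roll-up,
    linear mixed-effects differential abundance with nested random
    intercepts and a convergence-fallback cascade, Bonferroni
    correction, sample-specific GO index construction with mixed-model
    correlation, complete-linkage hierarchical clustering, and a
    synthetic-data generator that emulates the paired study design with
    censoring-driven informative missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, IRanges, lme4, lmerTest,
    ape, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, DifferentialExpression,
    GeneSetEnrichment, Clustering
RoxygenNote: 7.3.3
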