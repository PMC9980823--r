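Package: somtyper
Title: Metabotype Discovery from Plasma Metabolomes with Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Stratifies individuals into metabotypes from untargeted
    plasma metabolomics intensity matrices. Implements the matrix-level
    preprocessing used for LC-MS metabolomics (missingness prefiltering,
    total-signal correction-factor normalization, log transformation and
    down-shifted Gaussian imputation of left-censored values), batch
    training of a self-organizing map on a hexagonal lattice, k-means
    partitioning of the map codebook with Davies-Bouldin selection of the
    number of clusters, and downstream characterization of the resulting
    metabotypes (hybrid ANOVA/Kruskal-Wallis differential features with
    Benjamini-Hochberg adjustment, Spearman correlations with clinical
    covariates, and longitudinal pairwise contrasts). A synthetic-cohort
    generator with planted cluster structure, left-censored missingness
    and per-sample injection scaling supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
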