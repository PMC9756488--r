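Package: triomic
Title: Multi-Omic Integration of Gut Microbiome, Metaproteome and Virome in
    Longitudinal Case-Control Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for integrating 16S rRNA amplicon counts,
    stool metaproteome intensities, and virome detection calls from
    longitudinal paediatric case-control cohorts.  Implements
    taxonomy-guided amalgamation of low-prevalence OTUs, metaproteome
    prevalence filtering, variance-stabilizing normalization and Bayesian
    PCA imputation, virome detection categories, cubic-spline age
    deflation, multi-view group factor analysis with automatic relevance
    determination, random-intercept linear mixed models with case-by-time
    interaction tests and Benjamini-Hochberg FDR control, and
    repeated-measures correlation.  Ships a synthetic cohort generator
    with planted effects so every stage has a ground-truth test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
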