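Package: methylotype
Title: Epigenome-Wide Biotyping of Stress Disorder Cohorts from DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving epigenetic patient biotypes from Illumina
    450K-style DNA-methylation beta matrices and clinical feature tables.
    Implements probe filtering and correlation-graph region collapsing,
    recall-stability filtering, a resampled clinical-association screen,
    PCA+CCA construction of latent gene-clinical composites, LDA-based
    biotype assignment with a closed-form per-region score, covariate-adjusted
    empirical-Bayes moderated t-tests for differential methylation, pathway
    set dissimilarity clustering, and a resampling-based diagnostic marker
    panel search with linear-SVM classifiers and ROC/Youden evaluation.
    Includes a seeded synthetic-cohort generator emulating the statistical
    structure the pipeline assumes, for testing and method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    MASS,
    yaml
Config/testthat/edition: 3
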