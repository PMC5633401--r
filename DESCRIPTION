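Package: gconnect
Title: Genetic Connectedness Across Management Units from Pedigree and Genomic Relationships
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Measures genetic connectedness between management units (herds,
    cages, contemporary groups) under the animal-model BLUP framework. Builds
    pedigree (A), genomic (VanRaden G, G0.5, min-max scaled Gs) and hybrid
    single-step (H) relationship kernels, computes the prediction error
    variance-covariance structure of the mixed model equations by fixed-effect
    absorption, and summarises connectedness with the prediction error variance
    of differences (PEVD), the coefficient of determination of contrasts (CD)
    and prediction error correlations (r), including contrast, pair-average and
    group-ratio summaries, full-sib stratification and principal-component views
    of the pairwise statistics. Includes k-medoid clustering of kinship with
    silhouette-based selection of the number of clusters, cluster-to-unit
    allocation scenarios emulating designed levels of disconnectedness, and
    simulators (full-sib cage designs, multi-generation pedigrees, gene-drop
    genotypes) so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    cluster,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
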