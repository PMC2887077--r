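Package: hepaStage
Title: Molecular Staging of Liver Disease in Biliary Atresia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Molecular staging workflow for infant biliary atresia liver
    biopsies. Encodes ordinal histology grading of portal inflammation and
    fibrosis with differential-score group assignment, derives a
    differential-expression signature between histology-predominant seed
    groups (per-gene median normalization, fold-change filter, Welch t-test,
    Benjamini-Hochberg FDR), classifies remaining samples with a nearest
    shrunken centroid (PAM-style) model under ten-times ten-fold
    cross-validation with majority-vote assignment, and tests the resulting
    molecular groups against clinical covariates and transplant-free survival
    (Fisher exact, Wilcoxon, Kruskal-Wallis, Gaussian kernel densities,
    Kaplan-Meier and log-rank, logistic regression). Includes a synthetic
    cohort generator emulating the cohort structure the analysis assumes, so
    the full pipeline is testable without microarray data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
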