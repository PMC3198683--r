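Package: xenoquant
Title: Quantification Pipeline for Tumor Xenograft Combination-Therapy Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end quantification stack for preclinical tumor-xenograft
    studies of combined anti-angiogenic and anti-inflammatory therapy: exact and
    rank-based cohort outcome statistics (Fisher's exact test on metastasis
    incidence, Kruskal-Wallis on tumor weights, repeated-assay summaries),
    geNorm reference-gene stability ranking and normalization for qPCR panels,
    gene-set enrichment analysis with a gene-permutation null and a
    leading-edge odds-ratio filter, and fluorescence vessel morphometry
    (inscribed radius, microvessel density, skeleton branch/endpoint/length
    metrics). A seeded synthetic-data module generates cohorts, expression
    bundles, qPCR plates and rendered vessel images with known ground truth so
    every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
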