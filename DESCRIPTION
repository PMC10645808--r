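Package: ctcyto
Title: Mass-Cytometry Phenotyping of Circulating Tumour Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for single-cell mass-cytometry (CyTOF)
    analysis of circulating tumour cells (CTCs) enriched from blood:
    ArcSinh transformation, Gaussian acquisition-parameter clean-up,
    deconvolution of barcoded carrier, osmium-labelled control and
    enriched populations, rule-based CTC identification and patient
    positivity scoring, self-organizing-map clustering with elbow
    metaclustering, hierarchical grouping of clusters into epithelial,
    early-EMT and advanced-EMT subgroups, rank-based marker contrasts,
    cluster-composition PCA and clinical association tests, and
    simplified count-matrix comparators (median-of-ratios normalization,
    negative-binomial Wald differential expression, EMT-signature tumour
    classification). A seeded synthetic-data module emulates an enriched
    CTC cohort, including carrier/control cells, debris, healthy-donor
    background and companion gene-expression count matrices, so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    jsonlite,
    yaml,
    ape,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
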