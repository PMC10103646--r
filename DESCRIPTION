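Package: cnvpop
Title: Read-Depth CNV Region Discovery, Genotyping and Population
    Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-scale copy-number-variation analysis from
    window read-depth matrices: GC-bias correction and diploid scaling,
    candidate-window detection and merging into copy-number-variable regions
    (CNVRs), silhouette-gated genotyping, genomic-feature annotation against a
    gene model, principal component analysis of deletion/duplication/combined
    CNVR dosage matrices, and V_ST-based differential-CNVR scanning with
    top-percentile outlier selection and gene mapping. Includes a synthetic
    multi-population cohort generator with implanted deletion and duplication
    alleles so every stage can be exercised and validated without external
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
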