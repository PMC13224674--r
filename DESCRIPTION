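Package: nichecompare
Title: Comparative Single-Cell and Spatial Transcriptomics of Endometriosis Lesion Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing immune and stromal programs between
    endometriosis lesion subtypes (peritoneal and ovarian) against eutopic and
    control endometrium, combining single-cell RNA-seq and GeoMx-style spatial
    segment data. Implements cell- and segment-level quality control and
    normalization (log-normalization, Q3 segment scaling), a two-step
    differential test for sparsely expressed genes that separates changes in
    expressing-cell frequency from changes in expression intensity,
    patient-level pseudo-bulk aggregation with a transparent negative-binomial
    Wald differential-expression test, gene-set activity scoring, spatial
    ligand-receptor co-expression screening with composition-adjusted partial
    Spearman correlation, co-expression module detection, variance
    partitioning, signaling-network summaries and an operational
    immune-hot/immune-cold niche classification. A seeded synthetic-data
    generator reproduces the statistical structure of the study design for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    fgsea,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    DESeq2,
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
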