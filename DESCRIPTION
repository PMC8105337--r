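Package: myelotrace
Title: Clonal Tracing of Multiple Myeloma from Single-Cell and Linked-Read Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational pipeline for longitudinal multi-omics studies of
    multiple myeloma: per-cell somatic mutation mapping from barcode-tagged
    single-cell alignments, linked-read molecule reconstruction and haplotype
    assignment of somatic mutations with cis/independent pair classification,
    multi-caller somatic consensus and coverage/VAF filtering, threshold-based
    genotype calling with reference-panel PCA projection and ancestry
    classification, ordered five-level copy-number categorization with
    density-based subclustering, and plasma-cell subpopulation tracking across
    timepoints with pathway overrepresentation and enrichment-correlation
    grouping. Includes seeded synthetic-data generators with ground truth for
    every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rsamtools,
    GenomicRanges,
    IRanges,
    cluster,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    fgsea,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
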