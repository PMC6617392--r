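Package: clonalgap
Title: Copy-Number-Aware Clonality and Resistance-Gap Analysis for Tumor
    Sequencing Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the clonal composition of tumors from targeted,
    exome and circulating tumor DNA (ctDNA) sequencing. Implements
    copy-number-corrected cancer cell fraction (CCF) estimation, TP53-anchored
    ctDNA purity, per-driver cancer cell fractions and the per-sample
    resistance gap (the fraction of cancer cells without a detected resistance
    driver mutation). Also provides assay-specific somatic variant retention
    filters with a panel-of-normals artifact filter, ploidy and amplification
    calling from segmented allele-specific copy number, transcriptomic subtype
    assignment by centroid correlation and nearest-template prediction with
    switch detection, immune infiltrate scoring (cytolytic activity, signature
    means, single-sample GSEA), neoantigen peptide enumeration with a pluggable
    binding-rank predictor, and synthetic cohort generators with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
biocViews: Software, CopyNumberVariation, SomaticMutation, Sequencing,
    Transcriptomics, ImmunoOncology
RoxygenNote: 7.3.3
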