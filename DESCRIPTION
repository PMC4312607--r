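Package: polytag
Title: Digital Gene Expression Tag Profiling for Diploid and Allopolyploid
    Transcriptome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for NlaIII/MmeI digital gene expression (DGE)
    tag profiling: filtering of raw 21-bp CATG-anchored tag libraries into
    clean tags, tag-to-gene mapping with at most one mismatch, tags-per-million
    (TPM) quantification, Audic-Claverie differential-expression testing with
    Benjamini-Hochberg false discovery rate control, sequencing saturation
    analysis, mid-parent-value classification of non-additive expression in
    allopolyploids with parental-dominance breakdown, hypergeometric term
    enrichment, keyword filtering of annotated gene lists, and average-linkage
    hierarchical clustering of expression matrices. Includes a synthetic
    diploid/amphidiploid tag-library generator with ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
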