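Package: chdcnv
Title: Reassessment of Copy Number Variants of Unknown Significance in
    Congenital Heart Defect Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotation and reassessment pipeline for copy number variants of
    unknown clinical significance (CNV-US) in congenital heart defect (CHD)
    cohorts. Annotates CNVs against known dosage-sensitive regions, finds
    recurrent CNV regions and their smallest region of overlap (SRO), runs a
    protein-coding candidate-gene cascade based on haploinsufficiency scores,
    developing-heart expression and gene-function lists, scores lncRNA
    content at two expression tiers, and predicts TAD-related gene-enhancer
    rewiring (intraTAD dosage effects, interTAD deletion fusion, and
    tandem-duplication neoTADs). Includes a synthetic cohort generator with
    planted ground truth for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
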