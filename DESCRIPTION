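Package: lofcurate
Title: Curation of Predicted Loss-of-Function Variants and PVS1 Adjustment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auditable rule engine for curating predicted loss-of-function
    (pLoF) variants. Assigns evasion and artifact flags in three categories
    (predicted rescue by secondary sequence properties, uncertain biological
    relevance, potential technical artifacts), resolves a five-level verdict
    (LoF, likely LoF, uncertain LoF, likely not LoF, not LoF) by worst
    consequence precedence, and derives the maximum allowable ACMG/AMP PVS1
    evidence strength. Includes transcript/CDS coordinate arithmetic,
    nonsense-mediated-decay escape rules, SpliceAI delta-score interpretation,
    pext (proportion expressed across transcripts) filtering, multi-nucleotide
    variant and frame-restoring indel rescue detection, sequencing-artifact
    heuristics, readers for GTF/VCF/FASTA/BED inputs, a deterministic
    synthetic-fixture generator, and cohort-level summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
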