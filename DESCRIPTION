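Package: neojx
Title: Screening Tumor-Specific Splice Junctions for Cell-Surface Antigen
    Candidates
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects non-annotated exon-exon splice junctions
    (neojunctions) in cohorts of STAR SJ.out.tab junction tables, calls
    per-sample positivity from supportive read counts, locus read depth
    against the most dominant overlapping junction, and supportive read
    frequency, and screens candidates through a filter cascade for
    tumor-specificity (normal-cohort positive-sample rate), sharedness
    across disease groups, restriction to expressed cell-surface
    ("surfaceome") genes, and predicted protein consequence by in-silico
    translation (frame status, premature termination codons, transmembrane
    integrity, extracellular impact). Includes multi-region and
    primary/recurrent heterogeneity summaries and a synthetic cohort
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
biocViews: Transcriptomics, AlternativeSplicing, RNASeq, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
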