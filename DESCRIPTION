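Package: spliceNoise
Title: Quantification of Splicing Noise and Cryptic Splice-Site Usage from
    RNA-seq Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies de novo (unannotated,
    condition-exclusive) splice junctions from per-sample RNA-seq junction
    calls, scores donor and acceptor splice-site strength with
    maximum-entropy sequence models fitted to annotated sites, performs
    per-gene junction-gain statistics gated on stable expression,
    stratifies cohorts by splicing-noise burden, and computes PSI and
    delta-psi isoform metrics. Ships a seeded synthetic-cohort generator
    (genome, annotation, junction files, gene counts with planted cryptic
    splice sites) for end-to-end testing and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
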