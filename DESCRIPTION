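Package: circlenom
Title: CIRCLE-seq Off-Target Site Nomination and Exon-Skipping Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for nominating candidate CRISPR-Cas9
    cleavage sites from CIRCLE-seq sequencing experiments. Implements
    read-pair filtering by mean base quality, exact SAM flag-pair orientation
    (83/163 and 99/147), and deleted-region size; run-length-encoded coverage
    and bedGraph-style peak construction; negative-control peak subtraction;
    replicate intersection; log10 peak-height ranking; and protospacer/PAM
    annotation of surviving peaks. Ships a fully ground-truthed synthetic
    CIRCLE-seq assay simulator (circularized ~300 bp fragments cleaved at
    planted on- and off-target sites, 75 bp paired-end reads) so that every
    stage is verifiable without external sequencing data, plus scalar assay
    metrics: exon-skipping efficiency, reading-frame restoration arithmetic,
    and ddPCR copy-number-loss quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
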