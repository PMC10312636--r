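Package: loriso
Title: Variant-Aware Isoform Detection, Haplotype Phasing and RNA Editing
    Analysis for Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transcript isoforms from error-prone long cDNA reads by
    assigning reads to annotated transcripts under explicit splice-site
    fidelity rules and collapsing unassigned reads into novel models;
    integrates sequence variants into isoforms to call haplotype-specific
    transcripts without assuming diploidy; and quantifies A-to-I RNA
    editing from single molecules, including differential editing between
    conditions, type I/II hyperediting detection, and Fisher's-exact
    coordination tests between edits and between edits and splicing.
    Ships a seeded simulator that generates every input the pipeline
    consumes (genome, annotation, reads, alignments, variants, edits) so
    the whole workflow is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
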