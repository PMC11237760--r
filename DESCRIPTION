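Package: crisprCensus
Title: Census of Endogenous CRISPR-Cas Systems in Complete and Fragmented Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a repeat-centred census of endogenous CRISPR-Cas systems
    in bacterial genome assemblies, built around the high-GC myxobacterial case.
    Provides de-novo detection of CRISPR arrays (repeat-spacer-repeat structures)
    in complete or fragmented assemblies, classification of direct repeats into
    terminal-motif types (C/B/G/E/U) with hairpin diagnostics, spacer cataloguing
    and per-type statistics, ungapped spacer-to-protospacer target tracing with a
    match/mismatch score threshold, mismatch-stratified PAM inference with
    degenerate IUPAC consensus calling, synteny-based comparison of locus gene
    context between genomes, and a synthetic-genome simulator that plants arrays,
    protospacers and PAMs with an exact truth table for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
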