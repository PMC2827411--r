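Package: remapkit
Title: Transcript-Level Probe Remapping and Splicing-Index Analysis for
    3' Expression Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates transcript annotations from multiple databases,
    clusters transcripts into gene loci under four linkage definitions
    (coding-exon overlap, shared exon boundaries, shared intron boundaries,
    any exon overlap), remaps short oligonucleotide probes onto the genome
    and onto spliced transcript sequences, filters non-specific probes, and
    regroups the survivors into transcript-signature probe sets.  Provides
    the Splicing Index for calling alternative splicing between two
    conditions from probe-set level intensities, threshold-based selection
    of differentially expressed genes, a synthetic-data generator with
    machine-readable truth for every pipeline stage, and a command-line
    driver wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
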