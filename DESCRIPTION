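Package: pnaScreen
Title: Antisense PNA Design and Holo-Genome Off-Target Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs peptide nucleic acid (PNA) antisense oligomers against
    the translational start window of bacterial genes and screens them for
    off-target binding sites across one or more genomes (for example a host
    insect and its endosymbiont, scanned jointly as a holo-genome). Extracts
    the -5..+5 window around an annotated start codon, emits the
    reverse-complement PNA, finds every exact or k-mismatch occurrence of a
    query and its reverse complement, classifies each hit by genomic context
    (translational start site, CDS interior, exon, Shine-Dalgarno region,
    intergenic), and generates and validates mismatch-control PNAs. Includes
    a deterministic synthetic-genome fixture generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    utils,
    stats,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
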