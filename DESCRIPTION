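Package: geneDecay
Title: Pseudogene Detection and Gene Gain/Loss Reconstruction from
    Comparative Genomic Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene loss from comparative genomic sequence data.
    Predicts theoretical proteins by translating a locus from the
    conserved start codon to the first in-frame stop codon, calls
    frameshift indels and premature stop codons against an intact
    reference coding sequence, detects inactivating mutations shared
    across species, profiles tandem repeat domains by self-comparison
    dot plots, assigns orthology by reciprocal best hits with gene-order
    (synteny) support, and reconstructs gene gain and loss events on a
    species tree by maximum parsimony with calibration-based event
    dating. Includes a fully specified simulator that evolves a
    repeat-rich single-exon gene along a phylogeny with injected
    inactivating mutations and a ground-truth table, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
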