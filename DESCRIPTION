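Package: gssptools
Title: Proteogenomic Event Calling from Genome Search-Specific Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A proteogenomics analysis pipeline that turns identified-peptide
    tables, a genome and its annotation into called proteogenomic events.
    Builds six-frame genome and three-frame transcript ORF search databases
    with coordinate-bearing identifiers, applies class-specific target-decoy
    false discovery rate control separately to known and novel peptides,
    anchors orphan peptides to genomic coordinates as genome search-specific
    peptides (GSSPs, including spliced two-block placements across GT-AG
    introns), and classifies them into novel protein-coding regions, gene
    model revisions, alternative-splicing junctions and single amino acid
    variants with codon-level back-inference. Companion modules provide
    label-free differential protein expression with transcript-protein
    correlation integration, delta-mass modification annotation, and a
    synthetic-data generator with known ground truth for end-to-end
    evaluation.
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
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
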