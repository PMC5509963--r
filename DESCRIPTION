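Package: retrofinder
Title: Retrocopy Detection and Annotation from Protein-to-Genome Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls retrocopies (processed gene copies) of multi-exon
    protein-coding genes from protein-to-genome alignments, using intron
    loss at homologous protein positions as the diagnostic signature of
    retroposition. Called retrocopies are classified against known
    pseudogene annotations, linked to their parental genes, and assessed
    for open reading frame conservation (frameshifts and premature stop
    codons). Annotated single-exon coding genes of retropositional origin
    are recovered from proteome self-alignments. Expression evidence is
    attached from four sources: uniquely-mapped RNA-Seq reads (RPM),
    best-hit EST alignments, RNA polymerase II peaks and CAGE
    transcription start sites. Retrocopies from multiple species are
    grouped into ortholog groups by reciprocal overlap within
    whole-genome-alignment blocks. A seeded synthetic-fixture generator
    produces toy genomes with implanted retrocopies of known provenance
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    Rsamtools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
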