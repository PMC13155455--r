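Package: irtopo
Title: Detection and Topography of Perfect Inverted Repeats in Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects maximal perfect inverted repeats (IRs) in genome
    sequences and characterizes their genomic topography. Provides an
    exhaustive detector for IRs with configurable minimum arm length and
    maximum spacer length, dinucleotide-preserving shuffled control genomes
    (Euler-walk shuffle in non-overlapping chunks), enrichment statistics
    with paired effect sizes (Hedges' g with small-sample correction,
    paired and unpaired Cliff's delta), IR density across functional
    genomic compartments, positional enrichment profiles around
    transcription/translation start and end sites with two-stage bootstrap
    confidence bands, and intraspecific SNV burden in IR arms versus
    spacers under length-based and trinucleotide-context-adjusted null
    models. A synthetic-data generator produces genomes with planted IRs,
    gene models, variants and terminators so that every pipeline stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
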