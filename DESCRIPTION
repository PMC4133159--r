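Package: apaTE
Title: Transposable-Element Effects on Alternative Polyadenylation and
    Downstream Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking a transposable-element (TE) insertion
    near a polyadenylation signal to altered cleavage-site choice, transcript
    isoform abundance, enzyme activity and xenobiotic-stress survival in
    Drosophila. Provides a coordinate model for an antisense two-gene locus
    with TE insertions, a position-specific scoring-matrix scanner for
    polyadenylation signals (PAS) and downstream sequence elements (DSE)
    around annotated cleavage sites with insertion-effect prediction,
    standard-curve qPCR quantification with isoform decomposition,
    Michaelis-Menten kinetics with a replicates lack-of-fit test, acute and
    chronic survival statistics (odds ratios, log-rank), and seeded synthetic
    data generators so every stage is testable without external downloads.
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
    survival,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
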