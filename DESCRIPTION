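Package: strataclock
Title: Dating Recombination Suppression and Retroelement Insertions on
    Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing the degeneration of noncoding DNA
    between X- and Y-derived genomic regions after recombination
    suppression. Detects direct-repeat (LTR-retroelement-like) structures
    within a sequence and homologous blocks between an X and a Y sequence
    by seed-and-extend local search with Karlin-Altschul E-values;
    estimates pairwise nucleotide divergence under the Tamura-Nei (1993)
    model and synonymous/nonsynonymous divergence by Nei-Gojobori (1986)
    pathway counting with bootstrap standard errors; converts divergences
    to ages with the molecular clock T = k/(2r); maps X-linked markers by
    two-point linkage with the Kosambi function; and simulates the assumed
    evolutionary process (ancestral duplication at a recombination-stop
    time, clock-rate substitution, scheduled element insertions, indels)
    so that every stage can be validated by parameter recovery.
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
    Matrix,
    jsonlite,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
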