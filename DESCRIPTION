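Package: iesfinder
Title: Split-Read Detection of Programmed DNA Elimination Sites in Ciliate Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for pinpointing macronuclear (MAC) genome positions of
    internal eliminated sequences (IES) from germline micronuclear (MIC)
    sequencing reads. Builds a concatenated MAC reference with N spacers and
    coordinate liftover, quality- and vector-trims Sanger-style reads, aligns
    them with a built-in seed-and-extend local aligner (or ingests SAM),
    classifies reads into fully mapped, one-end-mapped and discontinuous
    categories, clusters one-end breakpoints into win1/win2/win3 candidate
    IES sites under a convergence window with a spanning-read veto,
    characterizes junction microhomology and TTAA motif content, assembles
    short IES from read extensions, annotates sites against gene models, and
    extrapolates genome-wide IES counts. Includes a synthetic MIC/MAC genome
    and read simulator with planted IES ground truth and an evaluation
    harness for precision/recall of the calling rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
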