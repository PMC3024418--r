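Package: HaploPop
Title: Haplotype-Based Population Genetics for Plastid Spacer Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Haplotype extraction and population-genetic analysis for
    non-recombining (plastid) spacer alignments. Scans pre-aligned regions
    into a typed catalog of mutational events (substitutions, indel events
    with unique spans, dinucleotide microsatellite repeat counts), collapses
    individuals into haplotypes, and computes Nei haplotype and nucleotide
    diversity with sampling variances, individual-based rarefaction, Hudson's
    Snn nearest-neighbour permutation test, Tajima's D and Fu and Li's D* and
    F* neutrality tests, the observed mismatch distribution, a
    homoplasy-constrained statistical-parsimony haplotype network, and
    parsimony scoring with simple indel coding (Fitch length, CI, RI,
    random-addition heuristic search with bound certification). Includes a
    structured-coalescent generator for island/mainland two-species sampling
    designs with known truth, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
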