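Package: pancora
Title: Reference-Agnostic Pan-Genome Consensus Ordering and Visualization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a reference-agnostic representation of a species
    pan-genome from multiple whole-genome-alignment output (XMFA or
    Mauve-style backbone coordinate tables). Alignment blocks are
    classified as core, dispensable or unique by the number of genomes
    they occur in; core blocks are arranged into a consensus ordering by
    a greedy approximation of the median permutation under Levenshtein
    distance, refined by local alignment against every input genome.
    Emits per-genome and consensus BED tracks (plain and gap-aligned),
    dot-plot point sets exposing inversions and translocations, and a
    synthetic pan-genome generator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ggplot2,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
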