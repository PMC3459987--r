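Package: tetherscan
Title: ChIP-Seq Fragment Coverage, piggyBac Element Annotation, and
    Regulatory-Domain Enrichment for Transposase Fusion Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing genome-wide binding of domesticated
    piggyBac transposase fusion proteins and its relationship to gene
    regulation.  Converts paired-end ChIP alignments to fragment-overlap
    coverage tracks, calls fragment clusters and summits, intersects peak
    sets from multiple callers into consensus peaks, annotates MER85/PGBD3
    repeat elements (TTAA target-site duplications, 13-bp terminal inverted
    repeats, the internal 16-bp palindrome) and classifies them as bound or
    unbound, scans DNA with IUPAC consensus motifs (TRE/AP-1, TEAD1, CTCF),
    builds orientation-corrected meta-profiles, performs GREAT-style
    binomial enrichment of peak summits in gene regulatory domains with
    permutation-based empirical false discovery rates, and classifies
    regulated genes from signal-log-ratio expression tables.  A synthetic
    data generator plants elements, motifs, genes, fragments and expression
    effects with known truth so that every stage of the pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    IRanges,
    S4Vectors,
    Biostrings,
    stats
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
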