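Package: chloroedit
Title: Chloroplast C-to-U RNA Editing Detection from Paired DNA/RNA Pileups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and quantification of C-to-U RNA editing sites in
    plastid transcripts by comparing DNA resequencing and strand-specific
    RNA-seq base-count pileups; codon-level annotation of editing effects;
    wild-type versus mutant differential-editing classification and
    per-transcript summaries; and the supporting genetics and phenotype
    arithmetic (Mendelian segregation chi-square with continuity correction,
    recessive-class fine-mapping interval delimitation, spectrophotometric
    chlorophyll formulas, 2^-dCt expression normalization). A seeded
    synthetic-data module generates toy plastid genomes, gene models and
    pileups with planted editing truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
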