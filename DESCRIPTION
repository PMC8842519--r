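Package: longfuse
Title: Gene Fusion Detection from Long Transcriptomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects gene fusions in long-read transcriptome sequencing
    (Nanopore cDNA, PacBio IsoSeq) from spliced alignments in PAF format
    and a GTF gene annotation. Reads are encoded as optimal exon chains by
    a co-linear chaining dynamic program; chimeric chains are filtered for
    overlapping genes, homologous gene pairs and segmental duplications,
    clustered per gene pair, and separated from library or basecalling
    random pairings by a one-tailed hypergeometric test with
    Benjamini-Yekutieli false discovery rate control. Read-through
    transcripts are recognised from gene proximity, fusion-to-normal
    expression ratio and exon junction structure. Includes a deterministic
    chimeric-read simulator and pair-counting Adjusted Rand Index
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
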