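Package: syntlink
Title: Microsynteny and Genetic Linkage of Gene Families Across Plant Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Traces genetic linkage of curated gene families (such as the
    circadian clock sMYB and PRR families) across plant genomes. Provides
    relative-best-hit (C-score) filtering of pairwise protein similarity,
    dynamic-programming chaining of homolog anchors into syntenic blocks,
    intervening-gene linkage scans with a permutation null model,
    Nei-Gojobori (1986) Ks estimation for dating syntenic blocks to
    whole-genome duplication events, and a genome-evolution simulator
    (polyploidy, biased fractionation, rearrangement, codon-level
    divergence) that emits standard GFF3/FASTA plus full ground truth, so
    the entire pipeline can be validated end-to-end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
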