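Package: paleofam
Title: Tracking Retention and Expansion of Gene Families Across Plant
    Paleopolyploidies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track how a motif-defined super-gene family (the
    extensins, defined by repeated Ser-Pro3/Pro4 units) has been retained,
    subfunctionalized and expanded across plant lineages with different
    paleopolyploidy histories. Provides motif-based family identification,
    paralog calling by alignment thresholds and ortholog calling by
    reciprocal best hits, codon-aware Nei-Gojobori (1986) estimation of dN,
    dS (Ks) and omega with Jukes-Cantor correction, Blanc-Wolfe median-Ks
    agglomerative clustering with neutral-rate dating of duplication
    events, collinear (syntenic) block detection with median-Ks assignment
    of blocks to whole-genome duplication events, tandem-duplication
    classification, a cross-species ancestral-locus retention matrix, and a
    forward genome-evolution simulator that emits every input format the
    pipeline consumes together with a ground-truth log.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
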