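Package: transppi
Title: Trans-Acting eSNP Source-Target Analysis on Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps trans-acting expression-associated variants (eSNPs in
    exons and in transcription factor genes) onto a protein-protein
    interaction network and characterises the resulting source-target
    gene pairs: genotype quality-control filters, per-SNP linear
    regression association scans with a 1 Mb trans definition,
    all-pairs network distances with an explicit disconnected-component
    convention, Louvain modularity clustering, cumulative topological
    trend profiles across association thresholds with edge-switching
    permutation nulls, and a battery of exact enrichment statistics
    (binomial cis-effect enrichment, Fisher and hypergeometric tests
    with Benjamini-Hochberg FDR, co-expression and positional-bias
    comparisons, cluster co-occurrence, binding-database membership,
    and path-annotation content tests). A synthetic-data generator
    plants cis-to-trans effect cascades, modular transcription-factor
    regulatory units and community-structured interaction graphs so
    the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
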