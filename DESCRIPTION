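Package: regevo
Title: Comparative Evolution of Promoters and Enhancers Across Mammalian Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the evolutionary turnover of tissue-active
    regulatory elements (promoters and enhancers defined by H3K4me3/H3K27ac
    ChIP-seq) across a dated species phylogeny. Builds reproducible consensus
    elements from replicate peak calls, projects them between genomes over
    block-wise orthology maps, calls cross-species conservation by reciprocal
    overlap, estimates class-specific turnover half-lives from exponential
    decay fits, identifies highly conserved, lineage-specific and recently
    evolved elements, assigns sequence ages for exaptation analysis, tests
    repeat-family and gene-set enrichments, and decomposes the variance of
    conservation over experimental and sequence features. Includes a seeded
    synthetic genome-evolution generator with full ground truth for
    calibrating and validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    ape,
    igraph,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
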