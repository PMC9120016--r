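Package: foldsector
Title: Dynamic and Evolutionary Sector Analysis of Protein Folds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrated analysis of protein conformational dynamics and
    molecular evolution for oligomeric folds. Generates constraint-based
    Cα conformational ensembles, extracts essential motions by principal
    component analysis, encodes conformers with a structural alphabet and
    builds normalized mutual-information coupling networks with eigenvector
    centrality, scores contact frustration against randomized-identity
    decoys, computes coevolution scores and real-valued Evolutionary Trace
    from multiple sequence alignments, compares phylogenetic trees by
    tip-distance correlation and clade composition, and overlays the
    dynamic, coevolutionary and energetic layers to partition a fold into
    interface-associated sectors. Includes seeded synthetic-data generators
    with planted ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
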