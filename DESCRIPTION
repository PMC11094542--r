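Package: crustassembly
Title: Community Assembly, Enzyme Stoichiometry and Co-Occurrence Networks
    for Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative inference chain for soil (biocrust) microbiome
    studies: eco-enzymatic stoichiometry (C:N:P enzyme ratios, vector length
    and angle, nutrient-limitation calls), abundant/rare taxon partitioning
    and copiotroph:oligotroph ratios, phylogenetic null-model community
    assembly (beta-MNTD, beta-NTI, Raup-Crick with Bray-Curtis, five-process
    partition), PERMANOVA/Mantel permutation tests, and co-occurrence
    networks thresholded by a random-matrix-theory criterion with module and
    complexity analysis. Includes a synthetic-data generator producing
    phylogenies, communities under named assembly regimes, soil metadata and
    enzyme activities with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    utils,
    vegan,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
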