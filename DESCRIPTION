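Package: wgdinfer
Title: Inference of Ancient Whole-Genome Duplications from Ks
    Distributions, Synteny Depth and Gene-Tree Duplication Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and place ancient whole-genome duplications
    (WGDs) in plant genomes. Builds node-weighted duplicate-age (Ks)
    distributions and finds significant peaks with a weighted Gaussian
    mixture model on log-Ks selected by a parametric-bootstrap likelihood
    ratio test; places peaks against ortholog divergences; chains
    family-based collinear anchors into synteny blocks and summarises
    syntenic depth ratios between genomes; and performs MAPS-style
    multi-taxon tests of WGD placement on collections of gene trees,
    comparing observed shared duplications against birth-death null and
    WGD-positive simulations with Fisher's exact tests and resampling
    intervals. A synthetic genome-evolution generator (birth-death gene
    families in a species tree, episodic WGDs with partial retention, a
    molecular clock with multiplicative noise, and polyploid gene orders
    with fractionation) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
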