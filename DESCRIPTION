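Package: egoperm
Title: Ego-Module and Signed-Pathway Permutation Inference for
    Label-Free Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Network-based selection of differentially expressed proteins
    and signed pathway-activity scoring for three-group label-free
    proteomics designs. A protein's ego-module (the protein plus its
    direct interactors in a protein-interaction network) is summarised by
    the mean and standard deviation of member log2 fold changes and
    compared against 1000 random same-size protein sets; between-contrast
    module Pearson correlations and signed pathway-activity sums (with -1
    weights for repressor members) are tested with the same random-set
    permutation null. Includes a fold-change filter with expression
    clustering, Y-maze and object-recognition behavioural scoring, and a
    synthetic-data generator that emulates the three-group study design so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
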