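Package: dicersite
Title: Multi-Class Prediction of Dicer Cleavage Sites in pre-miRNA Hairpins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the position of human Dicer cleavage sites
    within short sliding windows ("cleavage patterns") over pre-miRNA hairpin
    sequences. Provides readers for hairpin FASTA, Vienna dot-bracket
    structure and mature-arm annotation files; inference of cleavage sites
    from annotated mature miRNA arms; generation of multi-class labeled
    cleavage patterns and realistic or class-balanced pattern datasets with
    cross-validation folds; dual sequence/structure 3-mer token encoding;
    a dual-stream Transformer encoder network with attentional feature
    fusion, trained with AdamW, plateau learning-rate scheduling and early
    stopping; a full evaluation suite (top-k accuracy, macro and weighted
    F1, perfect match fraction, positional shift error, derived binary
    metrics); and a synthetic hairpin simulator with planted cleavage
    determinants for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
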