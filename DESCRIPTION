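Package: signalogr
Title: Orthology-Based Transfer of Signaling Pathway Membership
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts novel signaling pathway components ("signalogs") by
    transferring curated pathway membership between species through
    InParanoid-style ortholog clusters, following the workflow used for
    worm, fly and human signaling networks. Includes interolog derivation
    from known directed interactions, orthology-coverage statistics,
    overlap analysis against reference pathway annotation resources,
    five-level novelty classification, drug-target relevance scoring,
    orthodisease reporting, a deterministic synthetic dataset generator,
    packaged literature-derived fixtures, network export to SIF and
    GraphML, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
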