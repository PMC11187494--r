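Package: gesel
Title: Graphical Ensembling for Feature Selection and Biomarker Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble feature selection on co-selection and co-importance
    graphs. Multiple base selectors are run over cross-validation folds,
    their agreement is aggregated into a weighted feature graph, and a
    signature of k features is extracted by solving the Heaviest k-Subgraph
    problem exactly (branch and bound) or approximately (greedy). Includes a
    leakage-free classification pipeline with sanity/efficiency model
    selection rules, majority-voting baselines, network-based signature
    evaluation on a protein-protein interactome (disease-module distances
    and hypergeometric over-representation), and a synthetic-data generator
    with planted informative, redundant and noise features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
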