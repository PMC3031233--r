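Package: agemine
Title: Classifying DNA Repair Genes as Ageing-Related with Interpretable Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for discriminating ageing-related
    from non-ageing-related DNA repair genes. Builds classification datasets
    from heterogeneous gene annotations (Gene Ontology biological-process
    ancestor closures, protein-protein interaction partner counts and binary
    interaction indicators, DNA repair pathway membership, evolutionary-rate
    values, and tissue expression profiles), trains two interpretable
    classifiers (a C4.5-style decision tree with gain-ratio splits and
    pessimistic pruning, and a Naive Bayes model), estimates accuracy by
    stratified cross-validated AUC, extracts IF-THEN rules from trees, and
    scores rules and single-attribute patterns with an exact one-sided
    binomial enrichment test. A constructive synthetic-data generator with
    planted, documented signal makes every pipeline stage testable without
    external downloads.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
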