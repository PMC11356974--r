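Package: emnet
Title: Ectomycorrhizal Fungal Diversity, Co-Occurrence Networks and
    Plant-Soil Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline linking the ectomycorrhizal (EM)
    fungal communities of focal trees to neighboring plant richness across
    forest types. Computes alpha diversity (richness, Shannon, Simpson,
    Chao1, ACE), partitions Sorensen beta diversity into turnover and
    nestedness components, builds signed Spearman co-occurrence networks
    with per-sample induced subnetworks and a composite multi-complexity
    index, classifies node roles by within-module connectivity (Zi) and
    among-module participation (Pi), quantifies forest-type effects with
    natural-log response ratios, fits interaction linear mixed models and
    random-forest contribution estimates, and fits partial least-squares
    path models with bootstrap inference. A seeded synthetic-data generator
    with known coupling between plant richness, environment, bacterial
    community structure and EM diversity makes every stage testable.
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
    lme4,
    lmerTest,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
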