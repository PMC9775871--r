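Package: bilexnet
Title: Lexical Networks and Cross-Language Repetition Priming from
    Fluency and Reaction-Time Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds word-correlation lexical networks from semantic-fluency
    response tables (incidence matrix, pairwise correlation weights,
    spanning-tree backbone), computes their small-world and
    community-structure statistics, and validates them against
    Erdos-Renyi random-graph ensembles.  Also analyses long-term
    repetition-priming reaction times: participant accuracy exclusion,
    outlier trimming, log transform, priming-effect summaries, and
    linear mixed-effects models with backward stepwise selection of the
    random-effects structure.  Synthetic generators for both data types
    make every stage of the pipeline testable without access to raw
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
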