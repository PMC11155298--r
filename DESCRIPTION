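Package: bmdsplice
Title: Benchmark-Dose Modeling of Gene Expression and Splicing Dose-Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for transcriptomic point-of-departure
    analysis. Simulates seeded dose-response RNA-seq experiments (negative
    binomial gene counts and binomial splice-junction reads) with recorded
    ground-truth benchmark doses; normalizes and prefilters count matrices;
    calls differentially expressed genes and differentially spliced events
    (percent-spliced-in with a credible-interval confidence rule); fits a suite
    of continuous dose-response models (linear, polynomial, power, Hill,
    exponential) under constant variance with nested chi-square and AIC model
    selection; derives benchmark doses at a one-standard-deviation benchmark
    response with profile-likelihood confidence bounds and rejection filters;
    and aggregates gene-level results into pathway-level benchmark doses and
    points of departure via Fisher over-representation tests, for both
    expression and intron-retention modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    tools,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
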