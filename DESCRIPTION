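Package: ascount
Title: Empirical Bayes Analysis of Sequence Counts Without Replicates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects differential expression between two sequencing-based
    expression profiles (DGE tag counts, RNA-seq gene counts) when no
    replicates are available. A hierarchical binomial model with a Gaussian
    prior on the log fold change and a shifted-exponential prior on the
    expression level yields an empirical-Bayes shrinkage estimate of the
    log10 fold change for every gene, together with the posterior
    probability that the fold change exceeds a user-chosen threshold and a
    direct-posterior false discovery rate. Hyperparameters are estimated
    from the data by quantile matching and a robust interquartile-range
    estimator. Classical baselines (two-proportion Z-test with Bonferroni
    correction, Fisher's exact test), ranked-list overlap machinery, and
    synthetic count-table generators for method evaluation are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
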