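Package: ordinalcausal
Title: Causal Discovery and Ordinal Causal Effects via Latent Gaussian DAGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end causal analysis of ordinal data such as athlete
    training logs. Continuous variables are discretized into ordered levels
    with a kernel-density quantile-threshold rule and validated by one-way
    ANOVA; a directed acyclic graph over latent Gaussian variables is learned
    from the ordinal data by a structural-EM algorithm with Monte-Carlo
    truncated-normal imputation and penalized-score hill climbing; ordinal
    causal effects of interval interventions are computed analytically from
    bivariate-normal bin probabilities on the mutilated graph, with bootstrap
    distributions over resampled data. Includes seeded generators for
    synthetic latent-DAG and training-log-like data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
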