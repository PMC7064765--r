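Package: coralsml
Title: Temperature-Forced Network-Coupled Dynamics of the Coral Surface
    Mucus Layer Microbiome
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the microbial community of the coral surface mucus
    layer (SML) as a system of coupled logistic differential equations in
    which each taxon's growth rate responds to seasonal seawater
    temperature through a Gaussian thermal-performance curve and to the
    rest of the community through co-occurrence network coefficients.
    Provides rank-correlation (Spearman) co-occurrence network inference
    with significance and strength thresholds, eigenvector and betweenness
    centrality summaries, compositional similarity statistics (Bray-Curtis,
    SIMPER with fourth-root transform), a six-scenario grid crossing
    specific/generalized networks with fluctuating/constant temperature
    profiles per reef zone, model-versus-observation regression with a
    joint Wald test of slope one and intercept zero, and a synthetic-data
    generator (Gaussian copula with planted rank-correlation blocks) for
    fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
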