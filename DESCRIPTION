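Package: morbnet
Title: Multimorbidity Networks from Ising Graphical Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and interpretation of multimorbidity networks from
    binary disease-indicator cohorts using undirected graphical (Ising)
    models. Provides pairwise marginal odds-ratio screening with Holm
    family-wise error control, conditional-stratum table enumeration,
    graph structure learning by node-wise logistic regression with
    backward elimination under the extended Bayesian information
    criterion (EBIC), joint maximum-likelihood estimation of the Ising
    model on the learned structure, conditional odds ratios and Yule's Q
    edge strengths, topological analysis (density, closeness and
    betweenness centrality with min-max normalization), stratified
    sex-by-age subgroup networks with age-band balancing and formal
    edge-strength comparison, ICD-9-CM major-group mapping, and a
    seeded synthetic Ising cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
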