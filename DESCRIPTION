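Package: foodfitness
Title: Nestedness, Community Structure and Fitness Ranking of Country-Food
    Production Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing bipartite country-by-food-product
    production networks built from long-format production, import and
    population tables. Constructs binary and per-capita weighted
    country-product matrices, quantifies nestedness with the NODF
    statistic against a fixed-link-count random null ensemble, extracts
    tightly correlated country (or product) communities with a maximum
    spanning forest on a Dice-type similarity matrix, ranks countries and
    products with the coupled non-linear fitness-complexity iterative
    map, and fits heavy-tailed degree and fitness distributions
    (three-parameter Weibull, log-normal). A synthetic-data generator
    with planted country capabilities and product difficulties provides
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
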