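Package: wastingshocks
Title: Macroeconomic Growth Shocks and Child Wasting: Estimation and Projection
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how short-term macroeconomic growth shocks
    affect the prevalence of child wasting (acute malnutrition classified from
    weight-for-height z-scores) across low- and middle-income countries.
    Provides a seeded synthetic multi-country survey generator with a known
    planted elasticity, a three-step survey reweighting scheme (country
    under-5 population, survey-round balance, design weights), weighted
    linear probability models with country fixed effects and region-specific
    temporal effects, cluster-robust (sandwich) inference, mechanism and
    subgroup variants, and a counterfactual burden calculator that projects
    wasting prevalence and wasted-child counts from country-level growth
    shocks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
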