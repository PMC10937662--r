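Package: trophicflux
Title: Mass-Balanced Food-Web Flux Networks and Comparison of Ecosystem States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares mass-balanced (Ecopath-style) food-web models
    of an ecosystem in two states. Provides validated model containers,
    ecotrophic-efficiency mass-balance checks, consumption-flux networks and
    production-fate matrices, diet-based trophic levels, connectance and link
    density with node bootstrap, footprint and reach metrics tracing energy
    through all direct and indirect living pathways, Monte Carlo propagation of
    pedigree (CV-based) parameter uncertainty with Welch t-tests and Bonferroni
    correction, harmonization of two models onto a common group set with
    carryover-link pruning and difference networks, closed-form temperature
    scalings of biomass turnover and metabolic rate, and a seeded generator of
    balanced synthetic food webs for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
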