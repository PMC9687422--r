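Package: nemafauna
Title: Faunal Analysis of Soil Nematode Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genus-level soil nematode community analysis:
    trophic-guild and colonizer-persister (c-p) classification, density
    standardization to individuals per 100 g dry soil, the classical suite
    of ecological indices (Shannon-Wiener diversity, Pielou evenness,
    Simpson dominance, nematode channel ratio, Wasilewska index, maturity
    and plant-parasite indices, and the enrichment/structure faunal
    profile), treatment comparisons by one-way ANOVA with LSD post hoc
    tests and compact letter displays, balanced two-factor ANOVA for
    gradient-by-depth designs, and a stochastic generator of study-shaped
    synthetic communities for validation and teaching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
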