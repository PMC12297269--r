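Package: acoscale
Title: Ant Colony Optimization for Short-Form Scale Construction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs short versions of multi-factor Likert questionnaires
    with an ant colony optimization (ACO) search. Candidate item subsets are
    scored by a simple-structure confirmatory factor analysis fitted to the
    polychoric correlation matrix of the ordinal responses; model fit (CFI,
    RMSEA), McDonald's omega, the correlation between short-form and full-form
    sum scores, and the preservation of the factor correlation enter a sum of
    sigmoid pheromone functions that drives the search. Includes multi-run
    aggregation into best-pheromone and consensus scales, a highest-loading
    baseline selection, an ordinal factor-model simulator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
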