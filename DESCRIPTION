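Package: mobidom
Title: Social Mobility and Stratification Dynamics in Dominance Hierarchies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intragenerational social mobility in
    matrilineal primate dominance hierarchies from longitudinal agonistic
    interaction records. Builds annual win:loss matrices, derives rank orders
    by reversal minimization, measures annual mobility as one minus the slope
    of the rank-on-rank regression, classifies upward/downward/no-change
    transitions, tabulates tenure against mobility, and models long-term
    social stratification with a two-stratum (upper/lower half) Markov chain,
    including half-score assignment for odd group sizes, fractional
    transition-count estimation, matrix powers over doubling horizons,
    closed-form stationary distributions, and a convergence criterion for the
    limiting probabilities. A seeded agent-based simulator generates
    longitudinal group histories (demography, annual rank dynamics, dyadic
    contests) with the statistical structure such analyses assume, so the
    whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nortest,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
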