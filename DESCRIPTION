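Package: wealthineq
Title: Household Wealth Inequality in Under-Five Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying and decomposing household-wealth
    inequality in under-five deaths from child-level survey microdata.
    Provides weighted subgroup prevalence estimation, the WHO HEAT-style
    summary measures (difference, ratio, population attributable risk and
    fraction) with adverse-indicator truncation conventions, per-country
    risk-difference meta-analysis with the DerSimonian-Laird random-effects
    estimator, Mantel-Haenszel pooled odds ratios with heterogeneity
    statistics, variance-inflation-factor screening, a neighbourhood
    socioeconomic composite built by principal components, and a
    from-scratch Fairlie nonlinear decomposition of the poor/non-poor gap
    with randomization over covariate orderings and subsamples.  A
    synthetic multi-country clustered survey generator with known ground
    truth makes the whole pipeline testable without access to restricted
    survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
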