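Package: forageRR
Title: Longitudinal Genetic Analysis of Canopy Vegetation Indices in
    Perennial Forage Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating genetic parameters of biomass
    accumulation in perennial forage trials from plot-level multispectral
    vegetation indices measured repeatedly within harvest cycles.
    Provides vegetation-index and growing-degree-day computation, REML
    estimation of variance components for single-trait and bivariate
    plot models, random-regression growth-curve models on a normalized
    Legendre polynomial basis (including a scaled terminal yield record),
    time-resolved heritability and genetic correlation curves, relative
    selection efficiency for indirect selection, genotype plus
    genotype-by-environment (GGE) biplot analysis, and a growth-curve
    stability statistic linking instability in fitted growth to
    instability in harvested yield.  A synthetic-trial generator with
    fully recorded ground truth supports validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
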