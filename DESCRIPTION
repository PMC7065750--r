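Package: kelpcanopy
Title: Satellite Kelp Canopy Time Series and Kelp Forest Community Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating giant kelp (Macrocystis pyrifera) emergent
    canopy from multispectral satellite scenes by two-endmember spectral
    mixture analysis with per-image dynamic seawater endmembers, assembling
    site and regional canopy time series on 4-month trimesters (cloud
    filtering, proportional standardization, running means), and testing
    their climate forcing with lagged Pearson correlations and
    AR1-generalized-least-squares trend models. Also implements the
    community-ecology statistics used in kelp forest surveys: diversity
    indices (Margalef, Shannon, Pielou), the Index of Relative Dominance,
    Bray-Curtis dissimilarity, two-way PERMANOVA with permutation of
    residuals under a reduced model, pairwise permutation tests, principal
    coordinates ordination with species vector overlays, Pillai's-trace
    MANOVA, t-tests and chi-square composition tests. A synthetic-data layer
    generates multiband scenes with known canopy-fraction truth, lag-coupled
    climate series, and factorial community tables so every stage can be
    verified by parameter recovery.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    nlme,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
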