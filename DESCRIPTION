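Package: patrindex
Title: Patriarchy Index from Census Household Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Patriarchy Index, a 0-40 composite measure of
    family-based gender and generational inequality, from person-level
    census-style household microdata. Eleven demographic indicators
    (female headship, teen marriage, spousal age gaps, co-residence with
    the husband's kin, living arrangements of the elderly, child sex
    composition) are derived from relationship-to-head codes and
    within-household pointers, age-sex standardized, rescaled to 0-10
    scores and aggregated over four equally weighted domains. The package
    also provides the surrounding evaluation machinery: Guttman's
    lambda-6 reliability, Kendall's tau-b validity correlations,
    k-nearest-neighbour Moran's I and LISA cluster typing, Theil-T
    inequality decomposition, region-level outcome measures (relative
    female labor force participation, total modified Whipple age-heaping
    index), stepwise OLS decomposition regressions, and a synthetic
    household-microdata generator with known patriarchal parameters for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
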