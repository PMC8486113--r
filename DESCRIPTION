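Package: carcmort
Title: Mortality During and After Incarceration from Linked Administrative Registries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for estimating all-cause and cause-specific
    mortality during and after incarceration from linked administrative
    registries: deduplication of movement logs and fuzzy name linkage to a
    mortality registry, construction of censored exposure intervals and
    person-time denominators, disaggregation of binned age structure via
    truncated negative binomial fits, ICD-10 cause-of-death grouping,
    directly age-standardized rates with exact Poisson and F-distribution
    rate-ratio confidence intervals, and penalized-spline hazard plus
    Kaplan-Meier survival analysis. Includes a synthetic registry generator
    with known ground truth so every stage is testable without access to
    restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    mgcv,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
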