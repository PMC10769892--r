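Package: lifegap
Title: Life Expectancy Gaps from Matched Primary-Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mortality ratios, life expectancy at age 18, and
    years of life lost for a diagnosed subpopulation relative to matched
    comparison groups in primary-care electronic health records. Implements
    exposure density sampling of matched comparison participants, Lexis
    expansion of follow-up into single-year-of-age strata with time-varying
    age, Poisson modelling of age-specific mortality with linear and
    quadratic age terms, indirect standardisation with Byar confidence
    limits, period life tables in the style of the Office for National
    Statistics, and Monte-Carlo confidence intervals for life expectancy.
    Includes a seeded synthetic-cohort generator with Gompertz-Makeham
    adult mortality so the full pipeline can be exercised and validated
    without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
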