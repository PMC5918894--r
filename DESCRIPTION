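Package: crcscreen
Title: Microsimulation of Colorectal Cancer Natural History, FIT Screening
    and Programme Economics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-level microsimulation of colorectal cancer natural
    history along the adenoma-carcinoma sequence, with an organised biennial
    faecal immunochemical test (FIT) screening programme overlaid on the same
    simulated individuals (common random numbers). Includes a synthetic-data
    generator for life tables, demography pyramids and calibration targets; a
    derivative-free calibration engine fitting adenoma prevalence and
    age-specific cancer incidence; and a health-economics layer producing
    discounted cost-effectiveness results (ICER or dominance) and undiscounted
    budget-impact streams with colonoscopy demand projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
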