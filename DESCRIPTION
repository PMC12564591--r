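Package: isoqca
Title: Configurational Analysis of HIV Disclosure and Social Isolation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for small-N configurational analysis of HIV status
    disclosure and social isolation among people living with HIV. Builds a
    15-item Social Isolation Index from binary exclusion indicators, codes
    disclosure behaviour (breadth of disclosure and partner disclosure),
    classifies respondents into a four-quadrant disclosure-by-isolation
    typology, profiles cumulative and domain-specific burden by subgroup,
    and constructs crisp-set Qualitative Comparative Analysis (csQCA) truth
    tables with consistency and coverage. Includes a constraint-ledger
    solver that reconstructs a 17-record fixture reproducing every published
    marginal of the underlying pilot survey, and a seeded generator for
    arbitrary-size synthetic surveys with configurable subgroup prevalences.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
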