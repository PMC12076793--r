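Package: labcea
Title: Cost-Effectiveness Analysis of Hospital Microbiology Laboratory Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree cost-effectiveness model comparing an active
    hospital microbiology laboratory service against no microbiological
    testing for hospitalised patients with suspected bloodstream infection.
    Computes expected costs, deaths, hospital days, disability-adjusted
    life years (DALYs) and incremental cost-effectiveness ratios (ICERs)
    per 1000-patient cohort; runs probabilistic sensitivity analysis with
    Dirichlet, beta and lognormal parameter distributions; one-way
    deterministic sensitivity analyses and break-even threshold searches
    over laboratory cost and volume; and computes empiric-regimen coverage
    from antibiogram tables. Includes a seeded synthetic parameter
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
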