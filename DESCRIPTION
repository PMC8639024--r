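Package: asdsurv
Title: Records-Based Surveillance of Autism Spectrum Disorder Prevalence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reusable pipeline for multi-source, records-based active
    surveillance of autism spectrum disorder (ASD) among 8-year-old
    children, modelled on the CDC Autism and Developmental Disabilities
    Monitoring (ADDM) Network 2018 design.  Generates seeded synthetic
    populations and provider records, ascertains cases with the
    three-indicator case definition (clinician diagnostic statement,
    special-education autism eligibility, ASD ICD billing code),
    assigns census-tract socioeconomic tertiles, and estimates
    prevalence with Wilson score intervals, Katz prevalence-ratio
    intervals, relative-standard-error suppression, Pearson chi-square,
    Woolf homogeneity, Cochran-Armitage trend, and permutation tests
    for median differences, rendering the standard surveillance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
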