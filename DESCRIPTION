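Package: fefburden
Title: Future Excess Fraction Estimation of Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the future burden of disease attributable to current
    exposure using the future excess fraction (FEF) method, a lifetime-risk
    alternative to the attributable fraction that requires exposure
    prevalence in a single index year rather than historical exposure data.
    Builds single- and double-decrement life tables from age-specific
    mortality and incidence rates, converts a baseline population into a
    matrix of future person-years at risk, projects age-specific disease
    rates forward (constant or log-linear drift), and combines them into
    expected lifetime cases, lifetime risk, lifetime excess risk, the future
    excess number (FEN) and fraction (FEF) per stratum group. Includes a
    Levin attributable-fraction comparator, one-at-a-time sensitivity
    analysis, a synthetic-scenario generator, and an individual-level
    microsimulation oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
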