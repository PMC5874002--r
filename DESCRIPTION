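Package: mslife
Title: Multistate Life Tables for Disability-Free Life Expectancy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Continuous-time three-state (healthy / functionally limited /
    dead) Markov modelling of interval-censored panel data with exact death
    times and right censoring, covariate hazard ratios, and derivation of
    total, disability-free and disabled life expectancies with
    simulation-based confidence intervals. Includes a synthetic-cohort
    generator emulating a Latin American ageing-survey design (baseline
    interview plus two follow-up waves and registry-ascertained deaths), so
    that the whole pipeline can be exercised and validated without access
    to restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
RoxygenNote: 7.3.3
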