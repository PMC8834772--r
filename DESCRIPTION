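Package: apcburden
Title: Bayesian Age-Period-Cohort Projection of Cancer Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian autoregressive age-period-cohort (APC) Poisson
    models to registry-style tables of event counts and person-years,
    projects incidence and mortality counts and rates to a future horizon
    with 95% prediction intervals, and reports truncated age-standardised
    rates (European Standard Population), annual average percent change
    (AAPC), burden tables, and the Bashir-Esteve decomposition of the net
    change in case counts into risk, population-ageing and population-size
    components. Includes a synthetic registry generator with known APC
    structure for validation, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rjags,
    coda,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
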