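Package: bongaarts
Title: Proximate Determinants of Fertility via the Revised Bongaarts Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the four fertility-inhibiting indices of the revised
    Bongaarts proximate-determinants framework - marriage (Cm), contraception
    (Cc), postpartum infecundability (Ci) and foetal wastage (Cfw) - either
    from aggregate inputs or from DHS-style woman-level microdata, composes
    them multiplicatively into a total fertility rate, decomposes fertility
    inhibition in percent terms, stratifies the analysis by background
    covariates (region, wealth quintile, education, residence), and projects
    future fertility under contraceptive-prevalence scenarios.  Includes a
    synthetic survey-population generator whose implied indices are known in
    closed form, so every estimator is testable without external data, and a
    command-line interface for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
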