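Package: adamatrix
Title: ADA-M Data-Use Profiles, Validation, and Access-Request Adjudication
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An implementation of the Automatable Discovery and Access Matrix
    (ADA-M) v1.0 information model for machine-readable data-use conditions.
    Provides the concept registry (Header, Permissions, Terms and
    Meta-Conditions taxonomy), a typed Profile document model with the
    '[Obligatory]' condition-list micro-grammar, bit-stable JSON and key-value
    serialization dialects, the seven-rule Profile validator, a formulaic
    decision engine that screens discovery queries and adjudicates access
    requests with an explicit REFER boundary for non-formulaic cases, a seeded
    synthetic generator of Profiles and access requests, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
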