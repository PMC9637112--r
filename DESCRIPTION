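Package: svhcdrivers
Title: Drivers of Inclusion on the REACH Candidate and Authorization Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying what drives the listing of
    substances of very high concern (SVHCs) under the EU REACH Authorization
    program. Computes CMR and environmental hazard scores from GHS
    classification-and-labelling notification fractions, economic covariates
    (log10 tonnage band with sentinel rules, square-root transformed
    registrant-country counts) and a grouped publication rank from literature
    corpus matching; fits normalized logistic regressions reporting odds
    ratios with Wald confidence intervals, adjusted McFadden pseudo-R2 and
    per-variable likelihood-ratio tests; and ships a seeded synthetic registry
    generator so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
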