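Package: judimpact
Title: Counterfactual Impact Evaluation of Health-Litigation Technical Notes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the economic impact of health-technology-assessment
    technical notes on preliminary injunctions in health litigation against a public
    payer. Implements a two-stage counterfactual model (note direction, then
    injunction outcome given note direction) with exchangeable random-forest,
    sequential-logit and two-stage linear-probability backends; a per-case
    decision-change savings estimator with bootstrap point and interval estimates;
    program-level cost aggregation, reference-year price adjustment and
    return-on-investment calculation; note/decision agreement and citation
    statistics; and a seeded synthetic litigation-case generator emulating the
    heavy-tailed cost structure and covariate-driven decision processes the
    analysis assumes, so the full pipeline is testable without restricted court
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
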