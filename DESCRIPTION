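Package: socbayes
Title: Bayesian Models of Social Information Use Under Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a social estimation task in which
    participants revise a first estimate after viewing a peer's estimate
    and confidence rating. Implements a family of beta-count Bayesian
    observer models with precision weighting of own and peer information
    and a confidence-dependent stay bias, per-participant maximum
    likelihood fitting with BIC model comparison, model and parameter
    recovery diagnostics, a mixed-effects analysis of social information
    use, and model-based trial-level regressors (including
    Kullback-Leibler belief updates) exported as three-column event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
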