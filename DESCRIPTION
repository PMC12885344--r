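Package: confdrift
Title: Dynamic Post-Decisional Drift-Diffusion Modelling of Confidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and fitting of a dynamic drift-diffusion model of
    decision confidence in two-alternative forced-choice tasks. Evidence
    accumulates to a bound to produce a choice and response time, continues
    to accumulate during the post-decisional interval at a rescaled and
    possibly biased drift rate, and is mapped to a bounded confidence report
    through a logistic transform with additive and multiplicative criterion
    shifts. The package provides the trial-level generative model, a
    quantile-based chi-squared objective minimised by differential
    evolution, population-level simulations of three confidence-distortion
    mechanisms (accumulative, additive, multiplicative), preprocessing and
    exclusion rules for behavioural cohorts, regression analyses linking
    confidence and fitted parameters to individual-difference scores, and a
    synthetic-cohort generator used as the test bed for the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
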