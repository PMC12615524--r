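Package: extinctr
Title: Associative Learning Models of Compound-Cue Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trial-by-trial error-correction models of human predictive
    learning in super-extinction and deepened-extinction designs. Implements
    the elemental Rescorla-Wagner model, a configural Rescorla-Wagner variant
    with pairwise conjunction cues, and the Pearce configural model with
    similarity-based generalisation; maps associative strengths to response
    probabilities with a SoftMax rule; fits per-participant parameters by
    constrained multi-start Nelder-Mead maximum likelihood; and compares
    models with small-sample corrected AIC, Akaike weights, group AIC and a
    Dirichlet probability-best analysis. Includes a builder for the 179-trial
    three-group design, a synthetic-cohort generator, a performance-based
    inclusion filter, descriptive response curves and a one-at-a-time
    likelihood sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
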