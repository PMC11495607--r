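Package: mrpsup
Title: Multilevel Regression with Poststratification and Probability of
    Superiority for Ordinal Survey Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates population attitudes from non-representative survey
    samples by multilevel regression and poststratification (MRP) with Bayesian
    cumulative ordinal probit and categorical logit models, fitted by a
    data-augmentation Gibbs sampler. Pairwise Likert items are compared through
    the within-subject probability of superiority (PSup) with half-weighted
    ties, decided against a region of practical equivalence (ROPE) on the 95%
    highest density interval, and, for small convenience samples, through
    paired-permutation randomization tests selected under a cumulative c-value
    budget. A synthetic-data module generates a census-style poststratification
    table, selection-biased respondents, and ordinal responses from a known
    latent-variable truth, so the full pipeline and its calibration
    (ROPE false-positive rate, permutation false-discovery percentage) run
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    withr
Config/testthat/edition: 3
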