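Package: llrdss
Title: Difficulty Scoring and Intraoperative-Complication Risk Modelling for
    Laparoscopic Liver Resection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Halls difficulty scoring system (DSS) for
    laparoscopic liver resection and a complete external-validation pipeline
    for its primary endpoint, the intraoperative complication (IOC): per-level
    outcome summaries and association tests, a multivariate linear score
    model, a conditional-average (Gaussian kernel) regression model, and a
    Weibull cumulative-distribution-function mean risk curve with a
    Kolmogorov-Smirnov goodness-of-fit test.  A synthetic cohort generator
    reproduces the marginal structure of a published 128-patient validation
    cohort so that every pipeline stage can be exercised without access to
    confidential patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
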