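Package: policytextpanel
Title: Text-as-Data Measurement of Local Health-Insurance Reform and Panel
    Estimation of Its Effects on Out-of-Pocket Spending
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to measure locally heterogeneous health-insurance reform
    effort from policy-document corpora and to estimate its effects on
    individual out-of-pocket health spending. Documents are filtered by
    title relevance, summarised by their top TF-IDF keywords, and scored
    against a category lexicon with collocation qualification of
    semantically neutral keywords; categorised keyword frequencies are
    cumulated into prefecture-year exposure measures from each prefecture's
    scheme launch year. Estimators cover two-way (individual and year)
    fixed-effects regression, fixed-effects two-stage least squares with
    weak-instrument, overidentification and endogeneity diagnostics,
    linear-combination tests, interaction marginal-effects grids, and a
    two-part expenditure model. A synthetic-data module generates document
    corpora and unbalanced individual panels with fully known ground truth
    so the whole pipeline is testable without restricted survey data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
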