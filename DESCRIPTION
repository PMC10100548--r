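Package: airhurdle
Title: Bayesian Hierarchical Hurdle Models for Workplace Air-Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening occupational inhalation exposure from
    workplace air-sampling records. Implements a preprocessing pipeline for
    compliance air-monitoring data (sample-type filtering, unit conversion to
    log10 mg/m3, industry-code concordance mapping, per-inspection worst-case
    aggregation, outlier and sparse-subsector filtering, substance-level
    train/test splits), a two-stage Bayesian hierarchical hurdle model in
    which a logistic stage predicts detection and a linear stage predicts the
    detected log10 air concentration from an industry sector/subsector
    hierarchy and standardized physicochemical properties with two-way
    interactions, posterior prediction and screening summaries for
    substance-by-workplace pairs, evaluation metrics against null baselines,
    and a synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    withr,
    pROC,
    jsonlite,
    ggplot2
Config/testthat/edition: 3
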