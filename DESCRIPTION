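Package: idmeval
Title: Decision-Theoretic Evaluation of Identifier Mapping and Filtering Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates and compares identifier-mapping (IDM) and
    identifier-filtering (IDF) methods for integrating two high-throughput
    platforms measured on the same samples (for example microarray probeset
    signals and protein spectral counts). Cross-platform ID pairs are scored
    by an association statistic (Pearson or Spearman correlation) with
    per-pair measurement-error variances estimated by bootstrap; a
    constrained two-component normal mixture with known heteroscedastic
    measurement error is fitted by an expectation-conditional-maximization
    (ECM) algorithm; empirical-Bayes plug-in posterior probabilities of
    correct mapping with delta-method posterior variances are derived; and
    candidate methods, Boolean combinations thereof, and spectral-event
    quality thresholds are ranked by precision-weighted expected utility.
    A synthetic-data module generates two-platform expression data, candidate
    ID maps of controlled quality, and spectral event tables so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
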