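Package: deacpred
Title: Enzyme Substrate Site Prediction from Sequence and Functional Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enzyme substrate lysine sites (such as deacetylation
    targets of sirtuin-family enzymes) by combining one-hot encoded
    lysine-centered peptide windows with binary functional-annotation
    features selected by hypergeometric enrichment against a background
    proteome. Classification uses a voting ensemble of radial-basis-function
    support vector machines trained on shared positives and resampled
    negative sets. Includes a leakage-safe protein-level evaluation harness
    (sensitivity, specificity, Matthews correlation coefficient over
    repeated splits), vote-count ROC curves, a proportion-enrichment
    chi-squared comparison, and a synthetic-data generator so the entire
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
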