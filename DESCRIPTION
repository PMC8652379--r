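Package: kce
Title: Kinase-Cancer Concept Embeddings for Literature-Based Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts therapeutically relevant protein-kinase/cancer pairs from
    the biomedical literature. Normalizes concept-annotated abstracts into token
    corpora (MeSH-descriptor relevance filtering, PubTator-style concept
    replacement, stop-word removal and lemmatization), trains skip-gram
    negative-sampling concept embeddings, derives kinase-cancer evidence pairs
    from kinase-inhibitor activity tables and clinical-trial records, builds
    historical training/test splits, classifies difference vectors
    f(kinase) - f(cancer) with a random forest under randomized hyperparameter
    search, and evaluates with ROC/PR curves, threshold selection and a
    concept co-occurrence baseline. Includes a synthetic-data generator with
    planted kinase-cancer signal so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
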