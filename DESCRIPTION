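Package: termspace
Title: Distributional Semantic Models for Building Species-Name Terminological Inventories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing terminological inventories of species names
    from text corpora with distributional semantics. Provides dictionary-based
    multi-word term tagging, count-based context vectors weighted by the
    log-likelihood ratio, prediction-based embeddings (continuous bag-of-words
    and a GloVe-style global-vector model) trained with reproducible seeded
    single-threaded routines, additive composition of multi-word term vectors
    from their component words, cosine-similarity ranking of related names,
    ranked-retrieval evaluation (top-N accuracy, precision and recall at N,
    mean average precision) against reference standards, and a synthetic-corpus
    generator with planted synonym groups for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
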