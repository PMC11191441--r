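Package: cohortmapr
Title: Semantic Harmonization of Cohort Data Dictionaries Against a
    Common Data Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Maps arbitrarily named cohort-study variables (a name plus an
    optional free-text description) onto the reference terms of a common
    data model using a two-stage retrieve-and-rerank cascade. Sentences
    built from variable names and descriptions are embedded with a hashed
    character n-gram encoder, the K nearest reference terms by Euclidean
    distance are retrieved, a trained pairwise match classifier scores
    each (query, candidate) pair, candidates below a probability
    threshold are eliminated, and the winner is chosen by a weighted
    blend of classifier probability and normalized Levenshtein string
    similarity, optionally expanding the candidate set with previously
    curated variable-to-term mappings. Ships training-set construction
    (positive pairs from curated mappings, within-modality hard
    negatives, class weighting, train/test/validation splitting), a
    synthetic multi-cohort data-dictionary generator for offline
    benchmarking, an evaluation harness (top-1 accuracy, hit@K,
    configuration grids), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
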