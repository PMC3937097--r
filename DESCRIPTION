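Package: synsemble
Title: Ensembles of Random Indexing and Random Permutation Semantic Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds distributional semantic spaces from free-text corpora with
    Random Indexing (RI) and Random Permutation (RP), and combines several such
    spaces -- trained with different models, context windows, stop-word
    handling, and corpora -- into ensembles for extracting synonyms and
    abbreviation-expansion pairs from medical text. Includes every published
    combination strategy (subset re-ranking, score summing/averaging with and
    without rank normalization, and two-step multi-corpora combinations),
    rule-based post-filtering of candidate terms with fixed top-10 refill and
    dynamic cut-off modes, an evaluation harness (recall at k, rank-weighted
    precision, exact binomial sign test, frequency-threshold sweeps), and a
    synthetic-corpus generator that plants synonym and abbreviation pairs so
    the whole pipeline can be exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
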