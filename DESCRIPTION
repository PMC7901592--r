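Package: embedlex
Title: Clinical Lexicon Expansion from Open Word-Embedding Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building clinical concept lexicons by querying word-embedding
    sources for terms similar to seed clinical concepts. Reads and writes the common
    embedding file dialects (word2vec text and binary, GloVe, FastText .vec), ranks
    vocabularies by cosine similarity, scores returned candidates with interannotator
    agreement statistics (Cohen kappa, disagreement matrices) over a ten-class
    semantic annotation scheme, summarises candidates across sources (frequency
    weights, semantic-type distributions, modifier contrasts), expands seed lexicons
    with synonym-labelled candidates, and applies lexicons to clinical notes to
    report per-cohort feature-documentation proportions. A synthetic-data module
    generates embedding spaces with planted synonym structure, multi-annotator
    labelings with controlled agreement, and note corpora with planted concept
    prevalences, so the full pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
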