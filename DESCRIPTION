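Package: sentidict
Title: Dictionary-Based Sentiment Analysis of Social-Media Comment Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for dictionary-based sentiment analysis of
    public-health-topic social-media comment streams. Builds composite
    sentiment lexicons (polarity words, negation words, six-level degree
    adverbs, emoji glosses), expands them automatically with TF-IDF adverb
    ranking, TextRank seed-keyword extraction and SO-PMI polarity
    classification, scores comments with a word/sentence/comment additive
    scheme with multiplicative negation and intensity modifiers, and
    aggregates opinion over time (outbreak/fluctuation/recession stage
    segmentation) and geography (economic macro-regions). Includes a fully
    parameterised synthetic comment-stream generator with planted ground
    truth, and a Kendall's W concordance test for expert-panel agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
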