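Package: chatmine
Title: Text Mining of Two-Way Health Chat Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining transcripts of two-way text-message health
    services: a character n-gram naive Bayes language identifier for short
    bilingual (English/Swahili) messages with weekly dominant-language
    imputation, token normalization (spell-correction policy, lemma lookup,
    synonym collapsing, stop-word filtering), bigram-preemption frequency
    tallies stratified by demographic cohort, pairwise phi word-association
    tables, engagement-pattern classification, conversation segmentation and
    coded-conversation analytics, double-agreement intent-label resolution,
    privacy-preserving term-count export, and a synthetic chat-corpus
    generator with ground truth for parameter-recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    lubridate,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
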