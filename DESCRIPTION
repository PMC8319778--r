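Package: balex
Title: Linguistic Markers of Behavioral Activation in Text-Based Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures behavioral-activation (BA) constructs from therapy chat
    text. Builds BA word categories by expanding clinician-curated seed terms
    with skip-gram-with-negative-sampling word embeddings and cosine
    nearest-neighbor search, scores pooled patient messages with LIWC-style
    percent-of-words category counts (including a composite emotional-tone
    variable), and links the resulting linguistic markers to PHQ-9 depression
    severity with longitudinal mixed-effects models: severity-band summaries
    with bootstrap confidence intervals, a variable-subset model grid scored
    by R-squared and AIC, and per-group random-intercept-and-slope trajectory
    fits. Includes a synthetic chat-cohort simulator so the full pipeline is
    testable without access to private therapy transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
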