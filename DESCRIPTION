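Package: actibigram
Title: Activity Bigram Phenotyping for Minute-Level Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-minute accelerometer count sequences into
    categorical activity-state sequences (sedentary, low, moderate,
    vigorous), detects non-wear time, applies wear-time validity rules,
    and derives bigram and unordered-bigram (u-bigram) average-per-day
    frequency profiles describing how activity changes from one minute to
    the next. Provides swap-style linear regression models that relate a
    transfer of time between activity states, or of frequency between
    (u-)bigrams, to a continuous outcome such as body mass index, under a
    series of covariate adjustment sets. Includes a Markov-chain
    synthetic-cohort generator with a linear outcome model so the whole
    pipeline can be exercised and validated without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
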