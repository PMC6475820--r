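Package: querysignal
Title: Event-Anchored Analysis of Health-Related Search-Query Logs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for mining time-stamped search-engine query logs for
    health signals anchored on each user's first celiac- or gluten-related
    query: cohort construction with washout and eligibility filters,
    dictionary-based symptom and condition extraction, before/after
    query-ratio statistics and event-anchored temporal profiles,
    recipe-to-ingredient dietary-shift ranking, cross-validated
    classification of user interest, and a synthetic query-log simulator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table (>= 1.14.0),
    jsonlite,
    pROC,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
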