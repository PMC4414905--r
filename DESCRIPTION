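Package: hospmine
Title: Mining Hospital Service Quality Signals from Online Health Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A text-mining pipeline for extracting hospital service quality
    signals from online health-community messages. Provides dictionary-based
    hospital name extraction with stepwise edit-distance normalization of noisy
    surface forms (acronyms, abbreviations, misspellings), detection of six
    social-media-based service quality factors via keyword lexicons, sentence-level
    sentiment polarity with mood-flow classification of messages into four
    recommendation types, precision/recall/F1 evaluation against gold labels,
    region and time trend analytics, and a seeded synthetic corpus generator that
    produces gold-labeled test corpora with controllable noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
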