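Package: deidtag
Title: Neural De-Identification of Clinical Notes with a BiRNN-CRF Tagger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protected health information (PHI) in free-text clinical
    notes with a character- and token-level bidirectional recurrent tagger
    feeding a linear-chain conditional random field, and replaces detected
    spans with type tags or realistic surrogates. Supports the deployment
    scenarios a health organization faces: fully custom training,
    off-the-shelf cross-corpus application, partial customization from small
    labeled samples ("only B", "A then B", "A mix B"), and unsupervised
    adaptation through in-domain skip-gram embeddings. Includes recall-at-
    precision operating-point tuning via a not-PHI emission bias, token- and
    entity-level evaluation, a JSONL standoff corpus format, and a calibrated
    synthetic clinical-note generator so the whole pipeline is testable
    without access-controlled clinical corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
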