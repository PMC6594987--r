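Package: neuromine
Title: Named Entity Recognition and Active Learning for Neuroscience Literature Curation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating experimental information from the neuroscience
    literature. Provides offset-preserving tokenization with brat standoff and
    token-per-line TSV interchange, a deterministic rule and dictionary
    annotator (entity dictionaries, a unit gazetteer, numeric value detection
    and value-unit linking, parenthetical abbreviation detection with
    document-level acronym propagation), a linear-chain conditional random
    field tagger with N-best decoding and exact conditional probabilities,
    uncertainty-based active learning by normalized N-best sequence entropy,
    a bidirectional LSTM-CRF neural tagger with character-level word
    representations, strict and relaxed span evaluation, and a seeded
    generator of synthetic annotated corpora for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
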