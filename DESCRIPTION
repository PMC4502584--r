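Package: argram
Title: Probabilistic Activation/Recognition Grammars with Self-Description
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Parse, execute, and analyze probability-weighted activation/recognition
    grammars: stochastic context-free grammars without null symbol whose terminals are
    actuators (emit output) or sensors (match and consume input), executable in
    production, recognition, and mixed mode against pluggable environments including a
    bidirectional Turing tape. Supports quote/unquote self-description (describing
    grammars, the root grammar, metaphoric retargeting, dynamic composition),
    swarm-based selection and maximum-likelihood recovery of mixture weights, and
    compilation of any grammar to its neural-circuit graph (somata, synapses,
    autapses) with DOT export. Includes a command-line interface and the full set of
    worked example grammars as plain-text fixtures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
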