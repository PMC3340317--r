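Package: semprop
Title: Semantic Propagation for Biochemical Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compare, align and annotate elements of SBML biochemical network
    models by propagating MIRIAM-style semantic annotations across the network
    structure. Implements feature propagation (inferred per-element feature
    vectors over a biological concept space), similarity propagation on the
    cross-model pair graph, a greedy score-maximising model aligner, and an
    annotation predictor that matches propagated feature vectors against a
    leave-one-feature-out collection built from an annotated model corpus.
    Includes generators for the toy networks and removal benchmarks used to
    evaluate the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
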