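Package: regeval
Title: Synthetic Ground Truth and Null Models for Image Registration Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demonstrates that image similarity is not a valid surrogate for
    image registration accuracy. Generates synthetic copy-shift-paste scenes
    with a multi-valued ground-truth displacement field, implements the CURT
    rank-order pixel permutation null model, computes the RRMS, cross
    correlation and entropy-of-difference similarity metrics, evaluates
    correspondence error against admissible displacement sets, and produces a
    similarity-versus-correspondence dissociation report.
License: MIT
Encoding: UTF-8
Imports:
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
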