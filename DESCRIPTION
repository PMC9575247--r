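Package: dcgn
Title: Cancer Subtype Classification from Gene Expression with a Hybrid
    CNN-BiGRU Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies cancer subtypes from high-dimensional gene
    expression matrices with a hybrid deep network (DCGN) that chains a
    fully connected projection, two-dimensional convolutions, max pooling
    and a bidirectional gated recurrent unit, all under GELU activations.
    Includes SMOTE minority oversampling and optional random
    undersampling for class balancing, per-gene standardization,
    stratified train/validation/test splitting, a multiclass evaluation
    suite (weighted precision/recall/F1, Cohen's kappa, Hamming
    distance), a synthetic expression-data generator with known class
    structure, and a command-line interface. The network forward and
    backward passes and the Adam optimizer are implemented in base R so
    every layer is inspectable and deterministic under a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
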