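Package: phonoplan
Title: Compositional Geometry of Speech-Preparatory Neural Population Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how neural population activity encodes
    planned phoneme sequences. Implements diagonal-regularized linear
    discriminant decoding with cross-validated AUC, cross-time, cross-epoch
    and cross-position decoder generalization, displacement-vector
    representational geometry with leave-one-condition-out compositional
    prediction, position-specific ridge encoding models with coefficient
    cosine-similarity summaries, and electrode-level tuning statistics with
    FDR control. Includes a synthetic session generator with a known linear
    compositional ground-truth code (cross-position alignment,
    position-dependent gain, sequence-length and word-boundary axes,
    epoch-shared and epoch-private structure) so that every analysis stage
    can be validated by parameter recovery without real neural recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
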