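Package: frustum154
Title: Frustum-Pattern Feature Learning for sEMG Grasp Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hand-crafted learning network for classifying six basic hand
    movements (cylindrical, hook, lateral, palmar, spherical, tip) from
    two-channel surface electromyography. Implements the frustum pattern, a
    graph-based local ternary texture extractor on 7x7 reshapings of
    49-sample windows, together with 15 statistical moments computed on the
    signal and its absolute value; features are generated from the raw
    concatenated signal and from 153 subbands of a tunable Q-factor wavelet
    transform (TQWT) run with four parameterizations. Subbands are ranked by
    cross-validated misclassification, the best 20 feature vectors are
    merged, iterative neighborhood component analysis (INCA) selects the
    final feature subset, and shallow classifiers (1-nearest-neighbour with
    Manhattan distance, cubic-kernel SVM) produce the final 10-fold
    cross-validated predictions. Includes a seeded synthetic sEMG generator,
    a reader for the MATLAB files of the public basic-hand-movement
    repository, and evaluation reports with confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
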