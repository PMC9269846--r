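Package: ecgpursuit
Title: Sparse-Coding Pipeline for 12-Lead ECG Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for classifying 12-lead electrocardiogram
    records by cardiac disease class. Provides a multi-detector R-peak
    consensus algorithm (detector bank pooled across leads, median beat
    count, 1-D k-means peak localization), midpoint QRS segmentation with
    fixed-length resampling, orthogonal matching pursuit sparse coding
    against Gabor, alternating-minimization, and KSVD dictionaries, four
    segment-aggregation schemes (single, mean, max, voting) feeding
    classical classifiers, and an evaluation-metric suite. A synthetic
    12-lead ECG generator with exact R-peak ground truth and
    class-dependent beat morphology makes every stage testable without
    external data; records round-trip through WFDB files with
    PTB-XL-style metadata tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ranger,
    xgboost,
    e1071,
    rpart,
    nnet,
    caret,
    withr
Config/testthat/edition: 3
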