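Package: recurph
Title: Persistent Homology of Recurrence Plots for Time-Series Feature
    Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Topological feature extraction from univariate time series.
    A series is delay-embedded, its recurrence plot (the matrix of pairwise
    Euclidean distances between embedded states) is treated as a grayscale
    image, and zero-dimensional persistent homology of the sublevel
    filtration is computed on the cubical (V-construction) complex with a
    union-find elder-rule reduction. Persistence diagrams are vectorized as
    persistence images with a squared-lifetime weight and reduced by
    non-negative matrix factorization with multiplicative updates, yielding
    low-dimensional scores that separate periodic from chaotic dynamics and
    support classification of physiological signals. Includes simulators
    (Chua's oscillator via fixed-step fourth-order Runge-Kutta, the logistic
    map, labeled synthetic cohorts), ROC/AUC evaluation, and an end-to-end
    pipeline with a parameter-sweep experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
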