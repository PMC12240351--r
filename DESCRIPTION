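Package: entroqspr
Title: Entropy-Based Topological Indices and Curvilinear QSPR Models for
    Molecular Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes ten degree-based topological indices (atom-bond
    connectivity, Forgotten, geometric-arithmetic, harmonic, inverse sum
    indeg, first and second Zagreb, sum-connectivity, Sombor, Randic) and
    their Shannon-type entropy counterparts from hydrogen-suppressed
    molecular graphs, reduced to degree-pair edge partitions.  Fits the
    five curvilinear regression families (linear, quadratic, cubic,
    logarithmic, exponential) used in quantitative structure-property
    relationship (QSPR) studies, with the full goodness-of-fit block
    (r, r-squared, adjusted R-squared, standard error of estimate, F,
    p-value, coefficient confidence intervals), renders report tables,
    validates fitted or literature-coefficient models on held-out
    compounds, generates chemistry-like synthetic graphs and property
    data with known ground truth, and provides a cross-validated machine
    learning stage (random forest, support vector regression, gradient
    boosting) over the entropy-descriptor table.  Ships the descriptor
    and property tables for fourteen colorectal-cancer drugs plus two
    external validation compounds as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    ChemmineR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
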