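Package: catrans
Title: Calcium Transient Analysis and Drug-Response Classification for
    iPSC-Derived Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ratiometric (Fura-2 340/380) calcium
    transient recordings of induced pluripotent stem cell-derived
    cardiomyocytes under drug exposure. Detects beats with a
    derivative-phase peak recognition algorithm, computes a 12-variable
    morphological description of every peak, and classifies whole signals
    by signal-level leave-one-out cross-validation with peak-level
    majority voting over a configurable classifier zoo (nearest
    neighbours under eight metrics, discriminant analyses, CART,
    multinomial logistic regression, naive Bayes with kernel density
    estimation, random forests, and least-squares support vector machines
    with a hierarchical multiclass tree). Includes a synthetic signal
    generator with ground-truth beat annotations for end-to-end testing,
    confusion-matrix evaluation with class merging, and ggplot2
    visualisations.
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
    MASS,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
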