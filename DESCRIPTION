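Package: mitomix
Title: Bayesian Classification of OXPHOS-Deficient Single Muscle Fibres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies single skeletal muscle fibres (myofibres) as
    like-control or not-like-control in their oxidative phosphorylation
    (OXPHOS) protein abundance, relative to healthy control subjects.
    Implements a Bayesian hierarchical two-component linear mixture model
    with a control-data-driven prior pipeline and a Gibbs sampler, the
    legacy frequentist prediction-interval classifier, a ground-truth
    synthetic-data generator, and an evaluation protocol (confusion
    matrices, prior-sensitivity sweeps, train/validation splits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
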