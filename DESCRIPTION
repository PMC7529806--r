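Package: vpeca
Title: Variant-Aware Paired Expression and Chromatin Accessibility Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates paired time-course gene-expression and chromatin
    accessibility data with population-genetic selection scores to infer
    which regulatory elements (REs) are active, which are both active and
    under positive selection, and which TF-RE-target-gene interactions
    they drive. Provides per-SNP composite selection scoring (Fisher
    combination of Fst/iHS/XP-EHH/PBS with LD-score weighting), RE catalog
    construction from histone marks and chromatin loops, a three-component
    statistical model (logistic selection-status inference, per-time
    accessibility regression, and staged LASSO plus quasi-Newton expression
    modeling with cross-context correlation priors), regulatory-triplet
    network assembly and subnetwork extraction, supporting enrichment
    statistics, and a synthetic-study generator so the full inference chain
    is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    withr,
    glmnet,
    ggplot2,
    generics,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
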