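Package: ancestrymix
Title: Genetic Ancestry and Admixture Inference from Sparse Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers genetic ancestry and admixture proportions from sparse,
    error-prone genotype panels such as those called from single-cell RNA-seq
    reads. Provides genotype input/output and allele harmonization, reference
    panel quality control (minor-allele-frequency and missingness filters,
    windowed r-squared linkage-disequilibrium pruning), principal-component
    projection onto a reference panel, three ancestry classifiers (nearest
    centroid on principal components, random forest on principal components,
    and a supervised binomial-mixture admixture estimator fitted by
    expectation-maximization), a Balding-Nichols synthetic panel generator
    with genotype-error injection, and leave-one-population-out evaluation
    with Wilson confidence intervals and admixture-recovery statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
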