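Package: acarp
Title: Aggregated Conditional-Covariance Tests of Monotone Homogeneity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Omnibus tests of unidimensionality (monotone homogeneity) for
    binary item-response data, built by aggregating pairwise mean conditional
    covariances (MCCs) and their standardized Z statistics across all item
    pairs. Conditioning groups are deciles of a regression-weighted rest
    score estimated in a training sample (CARP conditioning), with
    Rosenbaum's unweighted pairwise rest score available as an alternative.
    Provides three estimators of the covariance matrix of the pairwise
    statistics (identity, sample moments, bootstrap), the chi-bar-square
    likelihood-ratio and conditional likelihood-ratio tests based on
    projection onto the nonnegative cone, preselected and conditionalized
    p-value combiners (Stouffer sum, Fisher product, Bonferroni), a
    compensatory two-dimensional 2PL simulator, and a Monte-Carlo harness
    for Type I error and power studies.
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
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
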