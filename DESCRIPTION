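Package: ctrlnet
Title: Graph-Theoretic Group Analysis of Control-Related Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for group-level graph analysis of resting-state functional
    connectivity among control-related brain networks (frontoparietal,
    cingulo-opercular, cerebellar and default-mode). Builds rectified Pearson
    correlation matrices from regional BOLD time series, thresholds them by
    correlation or sparsity with automatic threshold selection, computes global
    and nodal topological measures normalized against degree-preserving rewired
    null networks, performs covariate-controlled network-based statistic (NBS)
    permutation inference on connectivity differences, characterizes the
    anatomical-distance profile of significant components with a
    connected-component-matched resampling null, and relates network features
    to clinical scores via rank partial correlation and ROC analysis. Includes
    a synthetic two-group cohort generator with network-block correlation
    structure and a planted long-range hypoconnectivity component so the whole
    pipeline is testable without imaging data.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
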