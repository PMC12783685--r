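Package: mapscreen
Title: Phenotypic Activity and Mechanism-of-Action Profiling for Live-Cell Embedding Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for image-based phenotypic profiling of
    high-throughput live-cell screens represented as per-field-of-view
    embedding tables. Provides a synthetic plate generator with known batch
    effects and dose-time treatment effects, robust MAD normalization against
    DMSO controls combined with an iterative soft-clustering batch integration
    over experimental replica and field-of-view covariates, a resampled mean
    average precision activity metric with a DMSO null distribution and
    Cohen's d effect size, a nuclei-count bootstrap activity baseline with
    percent-inhibition effects, an incremental multi-dose multi-timepoint
    mechanism-of-action linear-probe classifier, and the self-supervised
    training-objective mathematics (cross-batch DINO centering, Barlow Twins
    decorrelation) at desk scale.
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
    arrow,
    ggplot2,
    glmnet,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
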