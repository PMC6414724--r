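Package: nichetransfer
Title: Temporal Transferability of Ecological Niche Models on Synthetic Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico framework for studying how the choice of environmental
    predictors (climate, land use/cover, ecosystem functional attributes),
    hierarchical regional-to-local integration, and species traits affect the
    performance and temporal transferability of ecological niche models.
    Generates two-epoch synthetic landscapes and virtual species with known
    suitability, derives the 19 bioclimatic variables, ecosystem functional
    attributes from vegetation-index time series and fractional land cover,
    fits AUC-weighted ensemble models over a registry of learners with
    split-sample replication, evaluates cross-validation and internal/external
    temporal transferability (AUC, sensitivity, TSS, kappa, Schoener's D), and
    explains accuracy variation with Gaussian GLMs under all-subsets AIC
    multimodel inference and Wilcoxon signed-rank trait contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    mgcv,
    MASS,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
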