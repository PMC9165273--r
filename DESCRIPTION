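Package: thyropet
Title: Quantitative FDG-PET/CT and Radiomics for Indeterminate Thyroid Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of [18F]FDG-PET/CT in cytologically
    indeterminate thyroid nodules. Computes SUVmax, SUVpeak and
    background-normalised SUV-ratios, segments nodules with a
    background-corrected 50%-of-SUVpeak isocontour, extracts the 107-feature
    standardised (IBSI-aligned) radiomic set plus total lesion glycolysis from
    PET and low-dose CT volumes, reduces dimensionality by redundancy
    filtering and maximum-likelihood factor analysis, trains elastic-net
    logistic classifiers evaluated in repeated stratified random splits with a
    corrected resampled t-test confidence interval, and performs rule-out
    threshold analysis (cut-offs at a sensitivity floor, exact Clopper-Pearson
    intervals, separate non-Hurthle and Hurthle cell strata). A synthetic
    phantom and cohort generator reproduces the statistical structure the
    analysis assumes, so the full pipeline runs without patient data.
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
    glmnet,
    jsonlite,
    pROC,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
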