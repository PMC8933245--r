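Package: quiqir
Title: Quality-Index Weighted Analysis of Quantitative MRI Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level analysis of quantitative MRI maps with per-image
    noise weighting derived from an image quality index. A motion
    degradation index (MDI, the standard deviation of R2* in white matter)
    is turned into per-subject variance estimates by restricted maximum
    likelihood (REML) over polynomial basis functions of the MDI, yielding
    weighted-least-squares mass-univariate general linear models that
    restore homoscedasticity. Includes R2* map fitting from multi-echo
    data, ELBO-based noise-model selection, voxel- and cluster-level
    familywise-error inference, heteroscedasticity diagnostics (polynomial
    R-squared, Engle ARCH tests, Kolmogorov-Smirnov normality), specificity
    and exclusion-threshold experiment harnesses, and a seeded synthetic
    cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
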