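Package: beescape
Title: Satellite Image Texture Metrics for Modelling Wild-Bee Biodiversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking spatial habitat heterogeneity, measured as
    image texture of a vegetation-index raster and terrain roughness of a
    digital elevation model, to wild-bee biodiversity sampled at trap
    points. Computes first-order (occurrence) and grey-level co-occurrence
    (GLCM) texture layers in a moving window, summarizes layers within
    ring buffers around traps, derives biodiversity responses (normalized
    bee counts, Shannon diversity, individual-based rarefied species
    richness with Chao1 extrapolation), screens predictors by
    distance-class and between-variable correlation and variance inflation,
    fits all-subsets linear models with AIC top-set model averaging,
    likelihood-ratio p-values and null-model variance comparison, and
    diagnoses residual spatial autocorrelation with permutation
    correlograms. Includes a synthetic landscape and bee-community
    generator so the entire pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0),
    tiff,
    vegan,
    withr
Config/testthat/edition: 3
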