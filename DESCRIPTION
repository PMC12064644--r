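Package: wingmorph
Title: Landmark-Based Geometric Morphometrics of Honey Bee Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based geometric morphometrics of honey bee
    forewings: generalized Procrustes alignment of 19-landmark configurations
    with tangent-space projection, colony averaging and transect chunking,
    principal component and principal coordinate ordination, permutation-tested
    multivariate shape regression and MANOVA, linear discriminant
    classification with leave-one-out cross-validation, pooled-covariance
    Mahalanobis distances between populations, Gaussian mixture model-based
    clustering with BIC model selection, and assignment of unknown samples to
    reference evolutionary lineages. Includes a hierarchical synthetic-data
    generator (populations, colonies, workers, digitization noise, latitude
    gradients) with known truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    mclust,
    vegan
Config/testthat/edition: 3
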