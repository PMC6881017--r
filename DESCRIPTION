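Package: loopmorph
Title: 3D Geometric Morphometrics of Brachiopod Long Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for species-discrimination analyses of 3D landmark and
    semilandmark data digitized on long-looped brachidia and similar curved
    skeletal structures. Provides generalized Procrustes superimposition with
    iterative sliding of curve semilandmarks by thin-plate-spline bending
    energy minimization, shape principal component analysis, canonical
    variate analysis with Mahalanobis distances and leave-one-out
    cross-validated classification, permutation-based Procrustes ANOVA for
    size, group and allometric-heterogeneity effects, and a landmark
    sampling evaluation curve (LaSEC) for judging how many landmarks an
    analysis needs. A synthetic loop-landmark generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    knitr
Config/testthat/edition: 3
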