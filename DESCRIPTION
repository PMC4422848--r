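Package: pubertwin
Title: Longitudinal Bivariate Twin Modeling of Hormone Levels and
    Voxel-Wise Grey Matter Density
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genetically informative longitudinal analyses of
    pubertal hormone levels and voxel-wise grey matter density in twin
    cohorts measured at two occasions.  Implements a four-phenotype
    correlated-factor ACE structural model (additive genetic, common
    environment, unique environment) fitted by full-information maximum
    likelihood to monozygotic and dizygotic twin pairs, latent-change
    covariance algebra, decomposition of phenotypic correlations into
    genetic and environmental contributions (rph-a, rph-c, rph-e),
    equality-constrained refits with likelihood-ratio tests, a
    mass-univariate voxel-wise driver with Benjamini-Hochberg false
    discovery rate control, preprocessing of urinary and salivary hormone
    assays (creatinine correction, two-day averaging, detection-limit
    handling, log transform, Mardia's multivariate normality test), and a
    synthetic twin-cohort generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
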