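Package: trajscreen
Title: Trajectory-Association Screening of Longitudinal Biomarker Panels
    Against Cardiac Function by Bivariate Linear Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens a panel of serially measured biomarkers (for example
    aptamer-based plasma proteomics) against serially measured cardiac-function
    variables (echocardiographic volumes and ejection fraction) by jointly
    modeling each (biomarker, outcome) pair with a bivariate linear
    mixed-effects model whose cross-outcome random effects may be correlated.
    The cross-outcome covariance block is tested by a likelihood-ratio test
    of the full against the block-diagonal random-effects covariance, with
    maximum-likelihood estimation under a log-Cholesky parameterization, a
    fallback ladder of random-effect structures (natural-spline, slope,
    intercept) for non-converging fits, and Benjamini-Hochberg false discovery
    rate control across the panel. Includes natural-spline trajectory
    descriptives, paired change tests, within-patient-mean Spearman summaries,
    and a synthetic cohort generator with known ground truth for calibration
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
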