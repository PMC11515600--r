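Package: fusemi
Title: Data Fusion with Multiple Imputation for Misclassification-Corrected
    Case-Control Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control analyses in which exposure is measured by
    biomarker testing in the case registry but only by self-report in the
    control survey.  The package harmonizes exposure measures across
    heterogeneous data systems, stacks the control survey with a validation
    survey holding paired self-report and biomarker results, multiply imputes
    the never-measured biomarker columns by chained equations, fits
    survey-weighted logistic regression with Taylor-linearization design-based
    variance, and pools estimates either by Rubin's rules or by bootstrap with
    multiple imputation using a Satterthwaite degrees-of-freedom
    approximation.  A synthetic-data generator with known truth (covariate
    margins, differential sensitivity/specificity of self-report, complex
    survey geometry) makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    ranger,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC
Config/testthat/edition: 3
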