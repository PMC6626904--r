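Package: cytofps
Title: Farthest-Point-Sampling Clustering and Penalized Classification
    for Mass Cytometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for paired-condition mass
    cytometry (CyTOF) cohort studies: event cleanup by a two-component
    Gaussian mixture on quality-control channels, farthest point sampling
    of pooled events into clusters with complete-linkage meta-clustering
    and rule-based immune subset annotation, extraction of basal medians,
    90% quantiles and stimulation-vs-basal arcsinh ratios of functional
    markers per meta-cluster, and lasso-penalized logistic classification
    of individuals under double leave-one-out cross-validation.  Includes
    a fully seeded synthetic cohort generator with planted group effects
    and ground truth for benchmarking, minimal FCS 3.1 input/output, and
    Mann-Whitney group comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    mclust,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
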