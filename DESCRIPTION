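Package: connectopo
Title: Functional Connectome Topology from ROI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparsity-thresholded binary brain networks from regional
    BOLD time series and analyses their topology: Pearson functional
    connectivity, binarization over a sparsity grid, small-world and
    efficiency metrics (clustering coefficient, characteristic path length,
    global/local/nodal efficiency) normalized against degree-preserving
    random-network nulls, AUC-over-sparsity summaries, Wilcoxon/FDR group
    comparison, and a LASSO-logistic nodal-efficiency classifier with
    ROC/Youden evaluation and repeated-subsampling internal validation.
    Includes a synthetic two-group cohort generator with modular
    small-world covariance structure for end-to-end testing without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    pROC,
    igraph,
    MASS,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
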