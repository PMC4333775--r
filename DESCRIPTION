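Package: restbn
Title: Directed Connectivity Among Resting-State Brain Networks via Gaussian Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns directed connectivity among resting-state brain networks
    from ROI time series using Gaussian Bayesian networks: sphere-ROI
    extraction from 4D volumes, band-pass filtering and nuisance regression,
    lasso-regularization-path candidate-parent screening, BIC-scored DAG
    hill-climbing with maximum-likelihood edge weights, cross-subject edge
    significance testing, and recursive-feature-elimination linear support
    vector classification of brain states from the directed-edge features.
    Includes a linear structural-equation-model simulator that generates
    multi-subject two-condition cohorts from ground-truth DAGs, optionally
    rendered into toy NIfTI volumes, so the full pipeline runs end-to-end on
    self-contained synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    e1071,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
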