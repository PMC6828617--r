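Package: fcmvpa
Title: Functional Connectivity Multivariate Pattern Analysis for Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for decoding experimental conditions from
    task-fMRI functional connectivity patterns. From block-design ROI time
    series it performs confound regression and band-pass filtering, builds
    per-subject per-condition ROI-to-ROI Fisher-z connectivity maps,
    classifies conditions with a linear support vector machine under
    leave-one-subject-out cross-validation (positive-connectivity FDR or
    F-score feature selection, one-against-one multi-class voting), assesses
    significance by label-permutation testing, and constructs discriminative
    and condition-preferring networks from consensus classifier weights.
    Includes a synthetic block-design BOLD generator with known
    condition-specific covariance structure and realistic confounds, so the
    whole pipeline is testable without access to acquired data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
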