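Package: semgrade
Title: Facial Nerve Function Grading from Bilateral Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated House-Brackmann grading of facial nerve function
    from bilateral facial surface electromyography (sEMG). Converts raw traces
    of seven facial poses into envelope amplitudes (rectification, 100 ms
    running-average smoothing, 500 ms maximum-activity epoch, 95th percentile),
    computes per-muscle lateralization indices, and classifies House-Brackmann
    grades under three clinical scenarios (normal vs. impaired, slight vs.
    moderate, three-class) with logistic regression, a radial-kernel support
    vector machine and distance-weighted k-nearest neighbours under
    leave-one-patient-out cross-validation. Includes a seeded synthetic cohort
    generator emulating the perioperative vestibular schwannoma recording
    protocol so the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    kernlab,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
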