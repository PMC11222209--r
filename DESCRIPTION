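Package: screwpose
Title: Automated Pedicle Screw Placement Accuracy from Paired CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automated measurement of pedicle screw placement accuracy
    and precision from paired pre- and postoperative computed tomography.
    Detects implanted screws by fitting a parametric shaft model to metal
    voxels, rigidly aligns each vertebral level across scans with an
    SVD-initialized, masked mutual-information registration, expresses
    tip, tail and mid-pedicle deviations from plan in a screw-aligned
    medial-lateral / anterior-posterior / superior-inferior frame, and
    rolls per-screw errors up into signed mean error, mean absolute error
    and 2-SD precision tables with regional comparisons. Includes a digital
    instrumented-spine CT phantom generator with full ground truth, plus
    bead-fiducial and perturbation validation of the registration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    minqa,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
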