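Package: eitclass
Title: Per-Element Classification for Electrical Impedance Tomography
    Bladder Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and per-finite-element classification workflow for
    2D electrical impedance tomography (EIT) of the urinary bladder. Builds
    triangulated torso cross-section meshes with boundary electrodes, solves
    the EIT forward problem by linear finite elements, generates labelled
    datasets of boundary-voltage frames for random bladder-like inclusions,
    trains one binary classifier per mesh element (elastic-net logistic
    regression, linear/quadratic/regularized discriminant analysis with
    optional principal-component reduction, and classification trees), and
    scores the reconstructed inclusion probability maps with a full suite of
    confusion-matrix, agreement (Cohen's kappa, McNemar) and image-quality
    (MSE, MAE, PSNR, SSIM) statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
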