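Package: octenhance
Title: Neural Enhancement and Quality Evaluation of Retinal OCT B-Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for denoising and contrast enhancement of retinal optical
    coherence tomography (OCT) B-scans with a compact encoder-decoder
    convolutional network, trained against frame-averaged ground truth with a
    combined mean-absolute-error and structural-similarity loss. Includes a
    synthetic layered-retina phantom simulator with speckle-like noise,
    vessel shadows, depth attenuation and N-frame averaging; the stochastic
    augmentation pipeline used during training; multi-network distillation
    into a synthetic training set; a test-time ensemble over unmodified and
    histogram-equalized inputs; objective quality metrics (Immerkaer noise
    estimation, window signal-to-noise ratio, SSIM, MAE, paired tests); and
    intergrader agreement statistics (Cohen's kappa per biomarker, Wilcoxon
    signed-rank on subjective quality scores).
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
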