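Package: tumorscan
Title: Brain MRI Tumor Detection with Anisotropic Diffusion, Texture
    Features and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for recognizing tumors in 2-D brain MRI
    slices: percentile contrast stretching, edge-preserving anisotropic
    diffusion denoising with an iteration-error stopping rule, first-order
    and gray-level co-occurrence matrix (GLCM) texture features, image
    quality metrics (SSIM, MSE, PSNR, Dice), brightness-threshold plus
    morphological tumor localization, and Gaussian-kernel SVM
    classification of normal versus abnormal slices. Ships a seeded
    synthetic brain-phantom generator with ground-truth masks so the whole
    pipeline is reproducible without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
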