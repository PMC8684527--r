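Package: focalfuse
Title: Multifocus Image Fusion with Sharpening Preprocessing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of registered multifocus images (two photographs of
    one scene, each with a different region in focus) into a single
    all-in-focus image. Implements three sharpening preprocessors (Laplacian
    filter, unsharp masking, and a hybrid Laplacian + discrete Fourier
    transform sharpener), four fusion back-ends (pixelwise average, pixelwise
    minimum, decimated discrete wavelet transform fusion, and stationary
    wavelet transform fusion with per-subband coefficient rules), an
    eight-metric full-reference quality suite (RMSE, PFE, MAE, entropy, SNR,
    PSNR, correlation, ERGAS), and a seeded synthetic multifocus-pair
    generator with known all-in-focus ground truth for end-to-end evaluation.
    A command-line interface exposes the full sharpen/fuse/evaluate pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jpeg,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
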