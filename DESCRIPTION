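Package: dmdstack
Title: Dynamic Mode Decomposition of Fluorescence Microscopy Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstruction, denoising, mode analysis and frame
    interpolation of fluorescence-microscopy image stacks (time series,
    3D z-stacks, polarimetry angle sweeps) by dynamic mode decomposition
    (DMD) and its delay-embedded higher-order variant (HoDMD). Includes
    singular-value hard-threshold rank truncation, amplitude-optimal mode
    fitting, prediction of unseen frames along the stack axis, a
    two-photon polarimetry analysis workflow, a synthetic phantom and
    point-spread-function simulator with Poisson noise, and image-quality
    metrics (PSNR, MSE, SSIM, integrated intensity, singular spectra).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
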