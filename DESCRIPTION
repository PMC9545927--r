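Package: rtflow
Title: Real-Time Spiral Phase-Contrast MRI Reconstruction and Flow Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a low-latency pipeline for real-time
    phase-contrast cardiac MR: variable-density golden-angle spiral trajectory
    design and audit, Kaiser-Bessel gridding NUFFT with iterative density
    compensation, velocity encoding and phase-difference flow imaging, a
    synthetic pulsatile aortic-flow phantom, paired corrupted/truth training
    data generation, compact 2D+time U-Nets for deep artifact suppression
    (complex-SSIM loss) and aortic segmentation (CLAHE preprocessing,
    BCE+Dice loss), sliding-window block reconstruction with a latency model,
    beat-to-beat stroke-volume and cardiac-output monitoring, and
    imaging/segmentation/Bland-Altman evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    EBImage,
    RNifti
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
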