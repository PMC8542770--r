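Package: fetalage
Title: Fetal Brain Age Prediction from Multiplanar MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts fetal brain age (gestational weeks) from multiplanar
    stacks of thick T2-weighted-like MRI slices using a 2D single-channel
    pre-activation residual convolutional network, test-time augmentation,
    and grouped-mode aggregation of the per-slice predictions. Includes a
    synthetic fetal-brain phantom simulator (gestational-age-dependent
    growth, cortical folding, ventricle prominence, slice-wise motion
    jitter, bias field, noise), an MRI slice preprocessing chain (brain
    masking, bias correction, denoising, resampling, zero padding, center
    slice selection), multi-channel and volumetric network variants for
    input-strategy comparisons, cohort-level evaluation (predicted age
    difference, random-selection tests, nonparametric comparisons), and
    gradient saliency with a brain-size scaling probe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
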