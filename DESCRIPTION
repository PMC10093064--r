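Package: protoseg
Title: Foreground-Prototype One-Shot Segmentation of Brain Tumor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Episodic one-shot segmentation of brain tumors on single-modality
    MRI. A shared convolutional encoder maps support and query slices to dense
    feature grids; a single foreground prototype is computed by masked average
    pooling of support features; query pixels are scored by a scaled negative
    cosine similarity against the prototype and converted to foreground
    probabilities by soft thresholding with a learned scalar. Training combines
    a class-weighted binary cross-entropy segmentation loss with a prototype
    alignment regularizer that swaps the roles of support and query. The
    package includes a synthetic MRI-like volume generator, the NIfTI
    preprocessing chain (intensity clipping, slice resampling, ROI cropping,
    label binarization, resizing, augmentation), episode sampling, the
    similarity/thresholding core, an end-to-end SGD training loop, and the
    volume-level evaluation protocol with Dice, IoU and precision metrics and
    k-fold aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
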