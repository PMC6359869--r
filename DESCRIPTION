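Package: microvasq
Title: Quantification of Bulbar-Conjunctival Microvessel Density from
    Paired Imaging Modalities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying superficial microvessel density of the
    bulbar conjunctiva from two-dimensional angiographic images. Implements
    a geometry-calibrated processing chain (field-of-view bookkeeping through
    resizing and cropping, translation-only registration, skeleton overlays),
    modality-specific preprocessing (histogram equalization, contrast-limited
    adaptive equalization, morphological background removal), a shared
    segmentation chain (Gaussian blurring, frequency-domain bandpass
    filtering, Otsu thresholding, Zhang-Suen skeletonization), and two
    skeleton-based density readouts: pixel-percentage density and the
    box-counting fractal dimension. Includes a seedable synthetic vascular
    network generator that renders one ground-truth network as paired
    coarse speckle-noisy angiogram-like and fine vignetted photograph-like
    images, plus paired-comparison statistics (repeated-measures/paired
    tests, Pearson correlation, Bland-Altman limits of agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Visualization, Preprocessing, Classification
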