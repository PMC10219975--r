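Package: duvtomo
Title: Virtual Serial Block-Face Deep-UV Microscopy and Cell Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward simulator and analysis chain for serial block-face
    deep-ultraviolet (DUV) surface-excitation microscopy of brain-like
    tissue. Generates ground-truth tissue and bead phantoms, renders
    block-face images under a Beer-Lambert depth-attenuation model with
    oblique-illumination shading and spectral mixing, plans tile grids and
    serial-section schedules, applies flat-field/colour/extended-depth-of-
    focus corrections, stitches mosaics by phase correlation, and recovers
    instrument parameters by bead FWHM profiling and 1/e optical-sectioning-
    thickness fitting. Includes nuclei segmentation, regional cell counting
    and density estimation over a region hierarchy, and the accompanying
    statistics (paired t, Welch ANOVA with Tukey HSD, Shapiro-Wilk).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
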