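Package: chemfuse
Title: Multivariate Fusion of Vibrational Spectroscopic Chemical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for combining chemical images (hyperspectral cubes) acquired
    with different vibrational spectroscopic modalities, such as infrared
    absorption and Raman scattering microscopy. Provides multivariate image
    registration of a high-resolution cube onto a low-resolution pixel grid
    (PCA target selection, histogram thresholding, bicubic resampling and
    gradient-descent affine optimisation), low-, mid- and high-level data
    fusion with PLS-DA pixel classification, multiblock co-inertia analysis
    with block contribution metrics, inter-modality Pearson correlation maps,
    cross-modality PLS regression prediction with error spectra, and
    pansharpening-style spatial resolution enhancement. Includes a synthetic
    phantom generator producing paired-modality cubes with known ground truth
    for every stage, and readers/writers for ENVI-style and CSV cube formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mixOmics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
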