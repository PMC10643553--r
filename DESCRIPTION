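Package: ptyroi
Title: Unsupervised Region-of-Interest Selection for Scanning X-Ray
    Diffraction Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Physics-informed, unsupervised selection of informative scan
    positions in ptychographic (scanning X-ray diffraction) datasets.
    Per-pattern transmission (absorption) and center-of-mass (scattering
    direction) features are mapped onto the scan grid, conditioned with a
    3x3 mean filter and natural-log scaling, and clustered with exact
    two-cluster 1-D k-means; the low-transmission and high-scattering
    clusters are combined into a region-of-interest (RoI) mask. Azimuthal
    segmentation of the diffraction patterns resolves anisotropic
    scattering from features smaller than the beam size. Includes
    conventional STXM, Hilbert differential phase contrast and
    computational dark-field baselines, RoI mask morphology (border
    growth/shrinkage, hole fill-in), a far-field forward simulator with
    Poisson noise for ground-truth validation, and TIFF/CSV stack I/O.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
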