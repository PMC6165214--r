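Package: fibreXRD
Title: Small-Angle X-ray Fiber Diffraction Analysis of Striated Muscle
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of small-angle X-ray fiber diffraction
    patterns from striated muscle. Provides a forward model that renders
    synthetic two-dimensional diffraction patterns of the myofilament lattice
    with known ground truth (hexagonal-lattice equatorial reflections with a
    disorder-decomposed width model, Bessel-function myosin layer lines, actin
    layer lines, meridional reflections, diffuse background and Poisson
    counting noise); detector-image reduction (quadrant folding, circularly
    symmetric background estimation, diffuse-background normalization, band
    projections); constrained multi-Gaussian equatorial fitting to extract
    d10, the I11/I10 intensity ratio and lattice-disorder widths; myosin
    layer-line fitting to extract integrated intensities, first-maximum
    positions and the myosin head radius Rm; and the derived physiology of
    ordered and recruited myosin head fractions, including intensity-tension
    regressions and Hill-versus-linear model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, minpack.lm, signal, jsonlite, yaml, tiff
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'fibreXRD-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'geometry.R'
    'synthgen.R'
    'imageprep.R'
    'equator.R'
    'layerline.R'
    'physiology.R'
    'io.R'
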