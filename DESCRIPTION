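Package: dermafiber
Title: 3D Dermal Fiber Microstructure and Uniaxial Stretch Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline linking the three-dimensional
    microstructure of dermal collagen and elastin fiber networks, imaged as
    two-channel multiphoton z-stacks, to the mechanical characteristics of
    uniaxial tensile stretch. Implements voxelwise 3D fiber orientation
    estimation by weighted vector summation over cubic windows, directional
    statistics for axial data including the 3D orientation index (mean
    resultant length), two-component axial von Mises mixture modeling of
    in-plane angle distributions, fiber volume-fraction measurement by
    intensity thresholding, J-shaped stress-strain curve parameterization
    (toe/heel/linear segmentation, moduli, midpoint strain), and
    distance-correlation dependence screening with permutation inference
    across per-sample feature tables. Ships a synthetic-data generator
    (fiber phantoms, stress-strain curves, cohort tables with planted
    dependencies) so that every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
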