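Package: vistar
Title: Analysis Stack for Label-Free Vibrational Imaging of Expanded Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative analysis of stimulated Raman scattering
    (SRS) imaging of hydrogel-expanded, protein-retained samples: bead-based
    resolution calibration with deconvolution of the bead object function and
    Rayleigh-criterion conversion, expansion-ratio estimation by log-polar
    spectral registration, protein-retention quantification with volumetric
    signal-dilution correction, and a label-free U-Net pipeline that predicts
    fluorescence-equivalent structural channels (nuclei, vessels, neuronal
    somata and dendrites) from a single protein-CH3 vibrational channel,
    evaluated by masked Pearson correlation. A seeded synthetic phantom
    generator (beads, multi-structure tissue phantoms, pre/post-expansion
    pairs) makes the whole pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
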