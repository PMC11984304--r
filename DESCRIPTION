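Package: paintsofi
Title: DNA-PAINT Blinking Simulation and High-Order SOFI Reconstruction
    with Localization Microscopy Quality Control
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates DNA-PAINT blinking movies with programmable
    oligonucleotide hybridization kinetics (repeat-motif docking strands,
    duplex-destabilizer shortened on-times, diffusive-imager background,
    sCMOS camera noise), reconstructs super-resolution optical fluctuation
    (SOFI) images from second- to sixth-order pixel-by-pixel cross-cumulants
    with subsequence drift correction, distance-factor flattening,
    Richardson-Lucy deconvolution and brightness linearization, and provides
    a minimal single-molecule localization branch (integrated-Gaussian
    fitting, uncertainty filtering, drift correction, averaged-shifted
    histogram rendering). Quality control includes image decorrelation
    resolution analysis, leave-one-frame-out jackknife SNR maps, filament
    cross-section FWHM, and resolution-scaled error/correlation scores.
    Multi-position grid acquisition can be simulated and stitched into
    large-field mosaics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
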