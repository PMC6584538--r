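Package: odtmorph
Title: Optical Diffraction Tomography Simulation and Label-Free Sperm
    Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates three-dimensional refractive-index phantoms of
    spermatozoa, synthesizes angle-scanned off-axis holograms under a
    first-order (Rytov-compatible) weak-scattering model, reconstructs 3D
    refractive-index tomograms via the Fourier diffraction theorem with
    iterative non-negativity regularization of the missing cone, and
    derives quantitative morphometrics: 2D head/midpiece/tail lengths
    from phase maps, and per-compartment volume, surface area,
    sphericity, dry-mass concentration and dry mass from tomograms,
    including decomposition into refractive-index bands and two-group
    statistical comparison of breed populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
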