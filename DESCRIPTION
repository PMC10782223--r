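Package: magcal
Title: Absolute Magnification Calibration for CryoEM from Gold Lattice Diffraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the absolute magnified pixel size of cryoEM micrographs
    from the position of polycrystalline diffraction rings (gold fcc/hcp,
    graphitized carbon) in their power spectra. Implements noise whitening of
    the power spectrum, sub-pixel ring-peak detection, azimuthally resolved
    ellipse fitting for anisotropic magnification, temperature-dependent
    lattice constants, a complementary spherical-aberration-based pixel-size
    estimator from aberration-refinement output, CTF-error analysis, and a
    synthetic polycrystalline-foil micrograph generator with known ground
    truth. Reads and writes MRC2014 images and RELION-style STAR files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
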