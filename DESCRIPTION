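Package: BraggSieve
Title: Background/Bragg Signal Separation, Sparsification and Peak Finding
    for Diffraction Frames
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates the smooth isotropic scattering background of 2D
    diffraction frames from Bragg peaks using weighted azimuthal statistics
    with Poisson, azimuthal (ring-variance) and hybrid error models, and
    iterative sigma clipping with a fixed or adaptive (Chauvenet-variant)
    cutoff. On top of the separation it provides lossy sparsification of
    detector frames (retaining only pixels above the background plus n sigma,
    stored with the radial background profile in an HDF5/NeXus container),
    densification back to dense frames with optional synthetic noise, an
    SNR-based Bragg peak finder with CXI-format output and a peak-count veto
    for serial crystallography, and a seeded generator of realistic synthetic
    frames with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
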