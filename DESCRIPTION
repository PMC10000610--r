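Package: coneroughness
Title: Contour-Slice Roughness Spectra and Grading for Conical Powder Heaps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the surface roughness (lumpiness) of cone-shaped
    powder heaps from triangulated 3D surface meshes.  The heap is sliced
    with equally spaced horizontal planes; each closed cross-section contour
    is fitted with a least-squares circle, unwrapped into a radial deviation
    profile e(theta) = R - r(theta), resampled onto a uniform angular grid,
    and analysed in the spatial-wavelength domain with the FFT.  The
    integral of the one-sided FFT magnitude over wavelength, Q, summarises
    the roughness energy of each layer, and per-sample vectors of layer Q
    values feed a second-order polynomial-kernel SVM that grades samples
    into four roughness classes with stratified cross-validation and
    confusion-matrix metrics.  Includes a seeded generator of synthetic
    lumpy cones (Gaussian radial bumps on an ideal cone) for testing and
    calibration, plus readers and writers for OBJ, PLY and STL meshes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
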