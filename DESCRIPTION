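Package: capforge
Title: Anatomically Derived, 3D-Printable Neuroimaging Head-Cap Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing 3D-printable EEG/fNIRS head caps from anatomical
    head surfaces. Computes 10-20/10-10/10-5 cranial landmark positions on a closed
    scalp mesh from five fiducials (nasion, inion, preauricular points and an
    initial vertex estimate) by iterative cross-section bisection, extracts scalp
    surfaces from volumetric images, builds wireframe cap lattices with
    normal-aligned grommet holes and ergonomic margin cuts, repairs the result
    into a watertight printable solid, and provides metrology utilities
    (circumference, geodesic landmark distances, radial projection, error
    statistics) for validating landmark accuracy. Includes synthetic phantom
    generators (spheres, ellipsoids, voxelized balls) with analytically known
    landmarks for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
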