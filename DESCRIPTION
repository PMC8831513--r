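Package: cavityPDT
Title: Monte Carlo Light Dosimetry and Treatment Planning for Photodynamic
    Therapy of Hollow Cavities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based Monte Carlo simulation of 665-nm light transport
    from an intracavity optical fiber in three-region (wall / cavity /
    surrounding tissue) geometries, and patient-specific treatment planning
    for methylene-blue photodynamic therapy of drained abscess cavities.
    Generates synthetic voxelized abscess phantoms (spherical, ellipsoidal,
    lobulated), reads and writes NIfTI-1 segmentation masks, maps methylene
    blue and Intralipid concentrations to optical coefficients, computes
    per-mW fluence-rate maps with a track-length estimator, and derives
    threshold optical power, optimal intracavity Intralipid concentration,
    and PDT eligibility over grids of optical properties, with paired
    nonparametric statistics for comparing planning strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
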