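Package: prostamould
Title: Patient-Specific 3D-Printable Prostate Biopsy Moulds with Calibrated Needle Guides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates patient-specific, 3D-printable moulds for ex vivo
    targeted needle biopsy of radical-prostatectomy specimens. Takes closed
    triangulated surface meshes (STL, millimetres) of a prostate boundary and
    one or more MRI-defined regions of interest, builds a material-optimised
    mould block with the prostate cavity subtracted and with cylindrical
    needle-guide channels aimed at each region's centre of mass, and
    calibrates guide-tower heights so that a fixed 50 mm needle insertion
    samples the target centroid. Includes a signed-distance-field geometry
    engine (surface offsetting, boolean subtraction, marching-tetrahedra
    remeshing), a seeded synthetic-phantom generator, a needle-targeting
    simulator with rigid placement-error models, and cohort summary
    statistics for a packaged 12-patient reference cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
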