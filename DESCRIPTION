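Package: anewall
Title: Near-Wall Hemodynamics from 4D Phase-Contrast MRI of Intracranial Aneurysms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies near-wall hemodynamic parameters in intracranial
    aneurysms from time-resolved three-directional phase-contrast MRI
    velocity fields. Provides velocity preprocessing (temporal phase
    unwrapping against the velocity-encoding limit, normalized-median
    outlier repair, lumen masking after rigid co-registration), vessel
    surface processing (Taubin smoothing, centerline extraction, aneurysm
    sac isolation, neck-plane fitting, sac morphometrics), flow-rate
    quantification through centerline-orthogonal planes with
    partial-volume correction and mass-conservation checks, wall shear
    stress estimation by normal-line velocity profile fitting together
    with time-averaged wall shear stress and the oscillatory shear index,
    and image quality metrics (signal-to-noise ratio by the two-image
    difference method and the velocity-to-noise ratio). A synthetic-data
    module generates analytic Poiseuille and Womersley pipe flows,
    sphere-on-tube aneurysm phantoms and phase-contrast-like noisy,
    velocity-aliased acquisitions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Matrix,
    RNifti,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
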