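Package: boneDVC
Title: Digital Volume Correlation and Peri-Implant Bone Analysis for In
    Situ Screw Pullout Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Local digital volume correlation (DVC) for time-lapse x-ray
    microtomography of trabecular bone around metal implants, with the
    downstream analysis chain used in screw-pullout experiments:
    subset-based subvoxel displacement tracking with NaN phase masking,
    Green-Lagrange strain on trilinear hexahedral elements (volumetric
    and maximum shear strain), repeated-scan error quantification,
    peri-implant morphometry (BV/TV in a cylindrical region of
    interest), screw insertion geometry, and pullout force-displacement
    curve metrics.  Includes a synthetic trabecular phantom generator
    with analytic ground-truth warp fields for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
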