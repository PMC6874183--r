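Package: pbsmu
Title: Volume-Based Secondary Monitor Unit Calculation for Scanned Proton Beams
Version: 0.1.0
Authors@R:
    person("Willis", "Deacon", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Secondary monitor-unit (MU) verification for single-field-uniform-dose
    (SFUD) pencil-beam-scanning proton treatment beams. The target is approximated
    as an equivalent cuboid from its volume and beam's-eye-view projected area;
    empirically tabulated output, depth and air-gap factors are interpolated and
    combined with a measured calibration to predict the MU required per beam.
    Includes voxel-grid ray tracing for water-equivalent depth, readers and writers
    for the factor-table and case interchange formats, comparison statistics
    against planning-system MU, and a self-consistent analytic toy beam model that
    generates factor tables and synthetic ground-truth cases so the whole method
    can be exercised without a treatment planning system.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
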