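Package: scalplayout
Title: Anatomically Anchored 2D Sensor Layouts for On-Scalp MEG and EEG
Version: 0.1.0
Authors@R:
    person("FIL Methods", "Group", email = "methods@example.org", role = c("aut", "cre"))
Description: Tools to map three-dimensional on-scalp sensor positions
    (optically pumped magnetometer MEG, EEG, or any on-scalp array) to
    anatomically veridical two-dimensional topographic layouts. The method
    digitally reconstructs the 10-20 electrode placement system on an
    individual's digitised head shape: a convex scalp mesh is built from
    head points and fiducials, on-scalp distances are measured by
    origin-crossing plane sections, the vertex Cz and the head circumference
    are located by iterative equidistance refinement, and each sensor is
    assigned an (eccentricity, polar angle) pair from ratios of on-scalp
    arc lengths. Includes a standard azimuthal (polar) projection baseline,
    a topographic interpolation and group t-map evaluation pipeline, and a
    synthetic head/array/field generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
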