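Package: wormfab
Title: Maskless Photopatterning Workbench for C. elegans Assays
Version: 0.9.0
Authors@R:
    person("wormfab", "developers", email = "wormfab@example.org",
           role = c("aut", "cre"))
Description: Tools for designing, simulating and analysing dynamically
    photopatterned C. elegans assays. Compiles parametric assay geometries
    (frames, micropillar arrays, T-mazes, spirals, corrugated channels) and
    freehand tablet strokes into binary DMD mask bitmaps with coordinate
    transforms, multi-exposure stitching and an optical-blur dose model;
    encodes empirical exposure/resolution calibration and hydrogel
    fabrication design rules; generates ground-truthed synthetic worm
    videos (undulatory locomotion, confinement-speed coupling, a hinge-pin
    lever mechanism, maze navigation); re-implements a frame-differencing /
    blob-moment video tracking pipeline with kinematics derivation; and
    provides assay statistics (speed summaries, maze choice tests,
    Kaplan-Meier survival with censoring) plus a closed-loop
    observe-decide-pattern experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
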