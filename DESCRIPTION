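Package: slicerQC
Title: Slicer-Independent Geometric Fidelity Assessment of FDM G-Code
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the geometry encoded in fused-deposition-modeling
    (FDM) G-code and quantifies its deviation from the reference STL model.
    The toolpath is parsed into staged point clouds, rasterized into a voxel
    label map, corrected for the nozzle-radius XY offset and the layer-height
    Z offset, registered to the reference frame through a co-sliced step
    calibration object (center-of-mass pre-alignment plus rigid ICP), and
    compared by signed surface-distance statistics (MSD, RMS, min, max) and
    by the volume of a watertight layer-extruded mesh reconstruction. A
    deterministic mini-slicer generates synthetic fixture scenes (perimeters
    plus rectilinear infill) so the whole pipeline can be validated without
    commercial slicing software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'stl-io.R'
    'gcode-io.R'
    'voxel-volume.R'
    'path-correction.R'
    'mesh-metrics.R'
    'registration.R'
    'layer-reconstruction.R'
    'synthetic-fixtures.R'
    'pipeline.R'
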