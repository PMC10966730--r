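Package: flytomo
Title: Time-Stepped Reconstruction of Continuous-Rotation (Fly-Scan) Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for the time-stepping interpretation of continuous-rotation
    (fly-scan) parallel-beam tomography. Simulates continuous acquisition of a
    time-evolving attenuation phantom (an enamel-like sample with a progressing
    acid-dissolution cavity), performs dark/flat-field correction and
    Beer-Lambert log transformation, enumerates and extracts overlapping 180
    degree projection windows from a single long scan, reconstructs each window
    by filtered back-projection with arbitrary start angles, and quantifies the
    temporal progression of demineralization via difference maps, threshold
    segmentation and cavity-volume-versus-time curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'geometry.R'
    'phantom.R'
    'acquisition.R'
    'timestep.R'
    'preprocess.R'
    'recon.R'
    'analysis.R'
    'config.R'
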