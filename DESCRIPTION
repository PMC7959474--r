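Package: handkin
Title: Agreement Analysis for Marker-Based and Markerless Finger Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for comparing finger kinematics measured by a markerless
    hand-tracking device against a gold-standard marker-based motion capture
    system. Provides a forward-kinematic hand model and a synthetic study
    generator emulating paired recordings (a constant-rate reference stream
    and a variable-rate, biased test stream), timeline reconstruction and
    uniform resampling of variable-rate streams, joint-angle, segment-length
    and range-of-motion computation from 3D joint-centre trajectories, and
    Bland-Altman agreement analysis with proportional-bias detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
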