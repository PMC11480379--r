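Package: tmjtrack
Title: Automatic Tracking of Mandibular Motion in Real-Time MRI
Version: 0.1.0
Authors@R: person("TMJ", "Tracking Contributors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tracks the moving mandible in dynamic (real-time) MRI of the
    temporomandibular joint. Mandible pixels are lifted to a 3D point cloud
    by treating the normalized grey value as a third coordinate, and a
    weighted point-to-plane least-mean-squares registration (nearest-point
    pairing, rigid fit, diagonal-scaling refinement) recovers the per-frame
    2D transform. Includes the two-landmark manual-tracking baseline, the
    dimensionless superimposition-error metric, condylar pathway and
    instantaneous-centre-of-rotation analysis with one-sided signed-rank
    threshold tests, and a synthetic phantom generator with ground-truth
    motion for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
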