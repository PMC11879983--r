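Package: gaitrec
Title: Sparse-IMU Gait Reconstruction with Planar Musculoskeletal Optimal Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs periodic sagittal-plane walking and running from sparse
    inertial sensor (accelerometer and gyroscope) recordings by solving direct
    collocation optimal control problems for a seven-segment, nine
    degree-of-freedom musculoskeletal model with 16 Hill-type muscles and
    penetration-based foot-ground contact. Virtual sensor signals computed from
    the model state are fit to measured per-cycle means weighted by their
    variance while muscular effort is minimized, yielding dynamically
    consistent spatiotemporal, kinematic and kinetic estimates. Includes a
    predictive (effort-minimal) gait generator and virtual IMU synthesis with
    configurable noise for offline evaluation of seven sensor placements, and
    waveform comparison metrics (RMSD, linear-fit-method coefficient of
    determination with Fisher-Z averaging).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
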