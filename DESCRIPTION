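Package: servonav
Title: Servo Navigation Simulator for Prospective Motion and Field Correction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale simulator and estimator/controller library for
    servo navigation in magnetic resonance imaging: prospective rigid-body
    motion and zeroth/first-order field correction from short 3D orbital
    k-space navigators. Provides an analytic ellipsoid phantom with
    closed-form k-space signals, orbital navigator trajectories, a linear
    perturbation model calibrated from eight navigator shots, a gain-one
    closed-loop servo controller with shim quantization, the
    echo-time-shifting parameter-bias correction with sliding-window
    updates, run-time moving-average filters, and high-pass-filtered
    precision metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
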