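Package: strikekin
Title: Strike Kinematics and Energetics of Trap-Jaw Spiders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for high-speed-video strike kinematics of
    trap-jaw spiders and similar latch-mediated spring actuation (LaMSA)
    candidates. Converts digitized point tracks of the closing chelicera
    into smoothed angular and linear displacement, velocity and
    acceleration profiles via penalized quintic smoothing splines, and
    derives rigid-rod energetics: moment of inertia, kinetic energy,
    strike power and mass-specific power output, with a muscle-power
    ceiling test for power amplification. Includes micro-CT morphometric
    post-processing (left/right averaging, carapace-width size correction,
    clypeus ratio) and a synthetic strike generator with analytic ground
    truth so every stage can be validated by parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mgcv,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
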