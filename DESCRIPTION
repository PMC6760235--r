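Package: specklephase
Title: Snapshot Quantitative Phase and Intensity Microscopy with a Coded
    Wavefront Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for snapshot quantitative phase imaging with a coded
    wavefront sensor, in which a random binary (0/pi) phase mask placed about
    1.5 mm in front of an ordinary intensity sensor converts wavefront slopes
    into speckle-pattern displacements. The package simulates the sensor
    physics (mask synthesis, band-limited angular-spectrum propagation,
    area-integrating pixel sampling), generates phantoms with analytic ground
    truth (microlens arrays, sinusoidal and constant-curvature wavefronts,
    torus-shaped cell optical-path-difference maps), jointly reconstructs
    sample amplitude and phase from a single reference/measurement image pair
    by regularized alternating optimization, provides classical
    slope-tracking and curl-free optical-flow baselines plus a
    transport-of-intensity solver, calibrates the mask-to-sensor distance,
    and digitally refocuses the recovered complex field.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
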