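Package: gravipursuit
Title: Ocular Pursuit and Interception of Targets Under Varied Gravities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis tools for occlusion-paradigm studies of
    whether an internalized earth-gravity prior guides smooth pursuit and
    interceptive timing. Generates parabolic target trajectories with linear
    air drag under scaled gravities, enumerates counterbalanced experimental
    designs, synthesizes surface-mapped eye-tracker gaze traces and
    button-press responses with known generative structure, processes gaze
    into scene-coordinate kinematics with threshold-based saccade
    classification and per-trial pursuit gains, computes corrected temporal
    errors together with 1g-extrapolation and central-tendency predictions,
    and performs linear mixed model inference with likelihood-ratio
    comparisons and simulation-based power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
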