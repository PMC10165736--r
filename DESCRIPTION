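Package: fatiguesim
Title: Multilevel Muscle Fatigue Simulation for High-Intensity Elbow Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates muscle force sharing and localized muscle fatigue for
    static and cyclic high-intensity elbow flexion tasks. Combines rigid-tendon
    Hill-type musculotendon mechanics, the revised three-compartment controller
    (3CCr) fatigue model, and inverse-dynamics-based load-sharing optimization,
    including a fiber-type, fatigue-weighted recruitment criterion that encodes
    the Henneman size principle. Provides subject-specific calibration of moment
    arms, maximum isometric forces and fatigue parameters from maximum voluntary
    contraction (MVC) traces, endurance time-to-failure prediction, full
    training-session simulation with rest and MVC blocks, EMG envelope
    preprocessing, and synthetic data generators for elbow models, hammer-curl
    kinematics and MVC gauge traces.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
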