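Package: shoulderelbow
Title: Scaled-Generic Musculoskeletal Model of the Shoulder and Elbow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scaled-generic musculoskeletal model of the human shoulder and
    elbow: an 11-coordinate, 9 degree-of-freedom thorax-clavicle-scapula-
    humerus-ulna-radius chain with two scapulothoracic gliding-plane
    (ellipsoid) constraints, Lagrangian inverse dynamics, obstacle-set muscle
    wrapping with geometric and tendon-excursion moment arms, quadratic-
    programming load sharing under a glenohumeral stability cone, and
    anthropometric scaling of body-segment inertial parameters, skeletal
    morphology, ribcage ellipsoids, glenoid orientation, and muscle
    physiological cross-sectional areas.  A deterministic synthetic-anatomy
    generator provides a complete right upper limb so that every analysis can
    run without external data, and a command-line tool exposes the main
    workflows (model generation, subject scaling, moment arms, abduction
    simulation, motion fitting).
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
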