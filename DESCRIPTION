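Package: hopexo
Title: Joint Mechanics of Hopping with a Passive Full-Leg Exoskeleton
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for lower-limb joint mechanics during
    stationary bilateral hopping with a passive, full-leg, parallel-elastic
    exoskeleton. Models degressive, linear and progressive spring stiffness
    profiles (including hysteresis and a body-mass stiffness prescription),
    generates dynamically consistent synthetic hopping trials (markers,
    per-leg ground reaction forces, exoskeleton attachment trajectories and
    analytic ground truth), and takes marker and force time series through
    zero-phase filtering, hop-cycle segmentation, sagittal-plane joint
    kinematics, link-segment inverse dynamics, decomposition of joint
    moments and powers into exoskeleton and muscle-tendon-unit
    contributions, average positive power distribution, and
    repeated-measures ANOVA with Sidak-corrected post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
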