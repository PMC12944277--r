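Package: gaitloop
Title: Gait-Phase Detection and Phase-Locked Stimulation for Rodent Treadmill Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hindlimb kinematics of mice walking on a
    treadmill, from pose-estimation landmark trajectories to joint angles,
    stance/swing/abnormal phase labels, spatiotemporal gait metrics, a
    lightweight three-class neural gait-phase classifier, and phase-locked
    charge-balanced biphasic stimulation waveforms for closed-loop
    neuromodulation simulation. Includes a synthetic sham/SCI gait generator
    providing ground truth for every pipeline stage, a streaming closed-loop
    simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    magrittr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
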