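Package: levercage
Title: Home-Cage Lever-Positioning Task: Controller, Kinematics and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop controller and analysis pipeline for an automated
    home-cage lever-positioning task for group-housed, RFID-tagged mice.
    Detects pull-and-hold trials in lever-angle traces, classifies them
    against acquisition (phase 1) and hold (phase 2) rules, advances a
    block-wise adaptive staircase on the required hold duration, extracts
    per-trial kinematic features (maximum displacement, hold slope, mean
    speed), summarises circadian and daily activity, and ships a virtual-mouse
    simulator so the whole pipeline can be exercised end-to-end without
    animals or hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
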