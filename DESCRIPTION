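Package: cagedose
Title: Closed-Loop Oral Drug Dosing for Group-Housed Mice with a Virtual
    Home-Cage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Control logic for an RFID-based home-cage device that weighs
    group-housed mice on a load cell and delivers a bodyweight-adjusted
    daily oral drug dose as 10 microlitre drops in response to licks at a
    spout.  Includes the robust mode-based daily bodyweight estimator, the
    lick-by-lick drug/water drop scheduler, the session state machine with
    lockout, exit-wait and automatic taring, plain-text event/weight/summary
    log writers and parsers, a discrete-event virtual cage (simulated mice
    with circadian drinking behaviour, noisy load cell, gravity valve and
    stepper syringe pump), and post-hoc analyses of dosing accuracy,
    circadian drinking structure and the drug-in-drinking-water comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
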