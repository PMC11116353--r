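Package: refitsim
Title: Closed-Loop Hemorrhagic-Shock Resuscitation with an In-Silico Porcine Test Bed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a physiologically based closed-loop controller for
    resuscitation of severe uncontrolled hemorrhagic shock (the ReFit
    algorithm): pulse pressure variation (PPV) guided crystalloid dosing,
    stepwise norepinephrine titration gated on dynamic arterial elastance,
    mean arterial pressure and heart rate start/stop rules, and a fixed-mode
    failsafe on loss of physiologic input. Ships a lumped-parameter porcine
    simulator of uncontrolled liver-laceration hemorrhage calibrated to
    published baseline hemodynamics and untreated natural history, an
    arterial-waveform feature extractor (MAP, HR, PPV, SVV, Ea_dyn, signal
    validity, hypotension trigger), and a scenario harness that closes the
    loop, injects transport and signal-dropout disturbances, and writes
    trend and command-ledger logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
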