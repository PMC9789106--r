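Package: photoshape
Title: Fibre-Photometry Analysis of Touchscreen Pavlovian Autoshaping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of fibre-photometry recordings made
    during a touchscreen Pavlovian autoshaping task. Provides a session
    scheduler and behavioural event-log generator, a multi-channel
    photometry trace simulator (sensor kernels, photobleaching, shared
    motion artifacts), the standard signal-conditioning chain (decimation
    to 100 Hz, 6 Hz low-pass, isosbestic least-squares correction, dF/F,
    peri-event trial extraction, per-trial baseline z-scoring), windowed
    AUC/peak/transient metrics against an endpoint-weighted baseline, and
    session-level behavioural summaries with signal-behaviour regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
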