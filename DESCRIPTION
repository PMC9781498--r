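Package: tracefc
Title: Individualized Estimation of Motor Skill from EEG Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating longitudinal change in motor skill from
    resting-state EEG functional connectivity. Implements tracing-error
    scoring of computer-based tracing trials against an eight-section
    quarter-ellipse track, a Morlet filter-bank connectivity stage
    producing peak-detected synchronization indices (phase clustering,
    spectral coherence, imaginary coherence, PLI and weighted PLI) for
    all electrode pairs, and a partial-least-squares correlation and
    regression procedure with permutation testing, bootstrap-consensus
    channel selection, statistical-power-constrained pruning and
    leave-one-out validation. A synthetic-data module generates EEG
    recordings with planted phase coupling and matching tracing trials
    so the full pipeline can be exercised without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
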