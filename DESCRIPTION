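Package: neurospeller
Title: Closed-Loop Auditory Neurofeedback Spelling from Intracortical Spike Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of a closed-loop auditory neurofeedback
    speller driven by intracortical multi-unit spike rates. Implements
    threshold-crossing spike detection on band-pass filtered voltage traces,
    binned spike counting and the trailing-window spike rate metric, per-channel
    rate normalization and mixing, linear rate-to-tone mapping, the
    hold-threshold yes/no decision state machine, feedback training paradigms
    with and without reward, a group-scanning auditory speller with a
    German-letter-frequency menu, session metrics (accuracy, spelling rate,
    Wolpaw information transfer rate), a seeded Poisson spike-train and intent
    simulator for desk-scale closed-loop experiments, and JSONL session logging
    with deterministic replay.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
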