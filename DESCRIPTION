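Package: wmpersist
Title: Detection of Working-Memory-Related Persistent Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting persistent, working-memory-related neural
    activity in trial-based electrophysiology and MEG experiments that contrast
    go/nogo delayed-comparison tasks with reversed memory loads. Implements
    task-design and trial-schedule generators, inhomogeneous-Poisson spike-train
    and local-field-potential simulators with planted delay-period effects,
    permutation tests for load-ratio and window-difference statistics,
    task/stimulus-specificity classification of units, differential-latency
    estimation in consecutive time bins, population-proportion contrasts, and
    log-geometric-mean source-waveform statistics for evoked-field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
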