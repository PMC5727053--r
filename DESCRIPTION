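Package: dfhm
Title: Dual Frequency Head Maps for Continuous EEG Mental Workload Indexing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Dual Frequency Head Map (DFHM) method for
    continuous, subject- and task-independent assessment of mental workload
    from multichannel EEG. The pipeline reads BrainVision or EDF recordings,
    bandpass-filters (0.5-40 Hz, linear-phase FIR), removes ocular artifacts
    by Infomax ICA with a pluggable component-rejection policy, re-references
    to the common average, and cuts the signal into 10 s segments overlapping
    by 5 s. Per segment, theta (4-8 Hz) and alpha (8-12 Hz) band powers are
    computed by FFT, z-scored against per-subject baseline statistics drawn
    from the first minute of each task, and fused into a head map that carries
    frontal theta z-scores and parietal alpha z-scores. Two RBF support vector
    machines (low-load and high-load detectors) are combined logically into a
    three-class workload index emitted every 5 s, summarised per task as
    portions of low/moderate/high-load segments, and compared across tasks by
    repeated-measures ANOVA with Greenhouse-Geisser correction. A synthetic
    EEG cohort generator with controllable frontal-theta/parietal-alpha
    workload signatures makes the full pipeline testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    ica,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
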