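Package: ctsrt
Title: Context-Tree Stimulus Generation and Reaction-Time Analysis for
    Serial Reaction Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for serial reaction time (SRT) experiments whose stimulus
    streams are generated by a probabilistic context tree (a variable-length
    Markov chain over a small alphabet). Provides tree validation, sequence
    simulation, event-type and last-variable-event labeling, analytic
    stationary event frequencies, a trial-level synthetic cohort generator
    with planted learning effects, trial filtering and cell-mean aggregation,
    and the statistical battery used in such studies: rank-transformed
    two-way repeated-measures ANOVA, two-way mixed (split-plot) ANOVA with
    Mauchly/Greenhouse-Geisser sphericity handling, Bonferroni pairwise
    follow-ups, per-subject sub-block slope tests, and simulation-based
    type-I error and power harnesses.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
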