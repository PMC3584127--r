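Package: facingbias
Title: Perspective Cues and the Facing Bias in Point-Light Walker Perception
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for psychophysical studies of
    the facing bias in biological motion perception. Synthesizes a
    gender-neutral 3D point-light walker, projects it with graded signed
    field-of-view perspective cues while keeping dot shape and size
    constant, generates randomized trial schedules, simulates observer
    cohorts (binary facing-the-viewer/facing-away responses plus reaction
    times), fits cumulative-Gaussian psychometric functions by maximum
    likelihood with Monte-Carlo deviance goodness-of-fit and parametric
    bootstrap slope intervals, and runs the group-level statistics: probit
    repeated-measures ANOVA, per-observer reaction-time polynomial fits,
    and the reaction-time/certainty Spearman correlation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
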