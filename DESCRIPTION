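Package: afmeg
Title: Behavioral and Neuromagnetic Analysis of Altered Auditory Feedback
    During Sequence Learning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing keystroke-level performance and
    magnetoencephalographic (MEG) evoked fields from piano sequence-learning
    experiments in which auditory feedback is occasionally altered at
    boundary or within-sequence ordinal positions. Provides a synthetic-data
    generator with configurable ground truth (keystroke streams, planar
    gradiometer recordings, toy forward models), behavioral metrics
    (inter-onset intervals, timing variability, post-feedback slowing,
    windowed error rates), paired Monte-Carlo permutation tests and
    synchronized-rearrangement 2x2 factorials with the PS_dep effect size,
    two-stage adaptive FDR control, spatio-temporal cluster-based
    permutation testing on combined-planar event-related fields, and L2
    minimum-norm source estimation with segment-wise contrasts and
    region-level reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
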