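Package: ciliokin
Title: Quantitative Ciliary Beat-Pattern Kinematics for Primary Ciliary
    Dyskinesia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-cycle kinematic analysis of ciliary beating from annotated
    high-speed videomicroscopy: twelve beat-cycle parameters (length, beating
    angle, global frequency, stroke and pause durations, tip distance and
    swept area per second, and their versions weighted by the fraction of
    beating ciliated edges), aggregation of 20-area epithelial edge scores
    into patient summaries, gold-standard partitioning of patients by nasal
    nitric-oxide output and transmission electron microscopy, empirical ROC
    analysis with named cutoffs, and a three-zone diagnostic classification
    for primary ciliary dyskinesia screening. Includes a synthetic
    beating-cilium simulator that renders grayscale image stacks, tracks the
    tip back out and auto-annotates beat cycles, so the whole pipeline can be
    exercised without patient video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
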