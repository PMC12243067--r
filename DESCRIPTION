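Package: brainctrl
Title: Functional Network Controllability Analysis for Clinical Brain Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes linear network-control metrics (average controllability,
    modal controllability, and minimum-energy activation cost) on functional
    connectivity matrices derived from regional resting-state time series, and
    runs the surrounding cohort analysis: a synthetic multi-subject generator
    with group-specific thalamo-cortical coupling effects, aggregation of
    region-level metrics to whole-brain, cortical-network and subcortical-nucleus
    levels, cognitive phenotyping (domain scores and impairment classification),
    covariate-adjusted permutation inference with false-discovery-rate control,
    and linear support-vector-machine classification of clinical status from
    thalamic controllability and volumetric features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    e1071,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
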