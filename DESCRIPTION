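Package: fnirsconn
Title: Block-Design fNIRS Activation and Functional Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-channel functional near-infrared
    spectroscopy (fNIRS) recordings acquired under a block design: subject
    specific band-pass filtering, dead-channel and motion-artifact
    exclusion, per-channel Z-scoring and task-block baseline correction,
    an accumulated cerebral-blood-flow activation measure, channel-wise
    functional-connectivity graphs (Pearson correlation, Fisher
    z-transformation, node strength), behavioural subgrouping by
    condition performance difference, and the associated group-level
    statistics (paired t tests, Tukey multiple comparisons, false
    discovery rate correction).  A synthetic cohort generator with
    planted hemodynamic, connectivity and behavioural effects makes every
    stage testable without access to raw device exports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
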