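Package: reflexio
Title: Decision Logic and Merging Statistics for Automated
    Crystallographic Data Reduction
Version: 0.1.0
Authors@R:
    person("reflexio", "maintainers", email = "reflexio@example.org",
           role = c("aut", "cre"))
Description: Standalone, testable re-implementation of the bespoke decision
    stages of a synchrotron macromolecular-crystallography auto-processing
    pipeline: per-shell merging statistics (R-merge, R-meas, completeness,
    multiplicity, mean I/sigma), automatic high-resolution-limit
    determination by I/sigma interpolation, Wilson-distribution outlier
    rejection with a re-merge pass, grouped multi-position merging with
    indexing-ambiguity resolution, anomalous-signal triage with SAD trial
    planning, and spot-wedge acquisition planning.  A synthetic
    reflection-data generator with Wilson-distributed intensities,
    counting-statistics noise, injected outliers and Friedel differences
    makes the whole pipeline exercisable without beamline data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
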