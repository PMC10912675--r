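Package: myoscore
Title: Continuous Single-Cell Differentiation Scores from Live-Imaging Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers a continuous per-cell differentiation score from single-cell
    motility and actin-intensity time series, as in live-imaging studies of
    myoblast differentiation and fusion. Tracks are partitioned into overlapping
    temporal segments, a fixed catalog of time-series features is extracted per
    segment, features are selected under Benjamini-Yekutieli false discovery
    rate control, and random-forest classifiers turn each segment into a
    confidence score for the differentiated state. Downstream estimators derive
    per-cell differentiation onset, duration and terminal-differentiation time
    from score trajectories, couple terminal differentiation to annotated
    fusion events, and compare condition groups with one-dimensional
    random-field-theory corrected two-sample t tests. A bundled trajectory
    simulator generates two-condition experiments (differentiating versus
    proliferating) with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
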