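Package: braindynet
Title: Continuous-Time Dynamic Functional Brain Networks from ROI BOLD Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds dynamic functional connectivity networks from
    region-of-interest BOLD time series. Sliding-window Pearson correlation
    produces observed network snapshots; an encoder/graph-ODE/decoder model
    (neural dynamics on complex networks) learns their continuous-time
    evolution and predicts per-volume interpolated snapshots inside the
    acquisition window and extrapolated snapshots beyond it. Snapshots are
    validated by small-world analysis against degree-preserving null models,
    and per-snapshot global clustering-coefficient series feed cross-validated
    classification of diagnostic groups. A seeded synthetic-data generator
    emulates modular, slowly varying BOLD covariance with controlled group
    effects so the whole pipeline is testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    e1071,
    class,
    pROC,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
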