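Package: sensorstore
Title: Hierarchical Storage and Pre-Aggregated Statistics for Biological
    Sensor Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-memory, file-persisted store for environmental and
    phenomics sensor time series organised in a four-layer hierarchy
    (user, experiment, node, stream) with metadata at every layer. Every
    stream maintains exact summary statistics (count, mean, standard
    deviation, minimum and maximum with occurrence times, last value)
    over fixed time-aggregation windows (1-minute, 15-minute, hourly,
    daily, monthly, yearly and overall), updated incrementally on ingest
    with a single-pass, mergeable moment accumulator, so that statistical
    queries at any aggregation level never rescan raw points. Includes
    CSV and batch ingestion, a JSON request router mirroring a RESTful
    contract, daily sensor-network quality-control reports (gap, range
    and missing-sensor detection), a seeded solar-irradiance simulator,
    and an operation-count latency benchmark against a brute-force
    group-and-recompute oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
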