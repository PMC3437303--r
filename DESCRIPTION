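Package: lanewatch
Title: Fuzzy-Inference Drowsiness Monitoring from Lane-Keeping Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts a stream of vehicle lateral-position measurements into
    crisp 0-100 driving-quality judgments through a Mamdani fuzzy inference
    system (triangular Ruspini partitions, a 5x5 safety rule matrix, and
    centre-of-areas defuzzification), maintains a per-driver reference
    distribution of judgments, and raises impairment alarms when the recent
    judgment distribution shifts downward or trends down.  A bundled
    lane-keeping simulator with a vigilance-decay and microsleep-lapse model
    generates ground-truthed test traces, and a command-line interface ties
    the pipeline together for batch use.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
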