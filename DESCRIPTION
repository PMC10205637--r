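Package: vpid
Title: Virtual Patient Identifiers for Anonymized Claims Databases
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Consolidates two churn-prone anonymized patient identifiers
    found in healthcare insurance claims into a virtual patient identifier
    (vPID) by merging identifier values that co-occur in identical claims,
    using a disjoint-set forest over the bipartite co-occurrence graph.
    Provides an evaluation framework that scores any claim-level identifier
    against enrollment-history ground truth with patient-level
    identifiability and traceability scores, a synthetic claims-world
    simulator reproducing the churn mechanisms that break naive identifiers
    (insurance changes, name changes, simultaneous changes, clerical typos,
    shared twin identifiers, garbage sentinel values), readers and writers
    for the delimited claim and enrollment tables, and a command-line
    pipeline for simulate, link, evaluate and histogram steps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
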