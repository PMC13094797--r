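Package: studyflow
Title: Configuration-Driven Data Management for Multicenter Epidemiologic Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A workflow-oriented information management toolkit for
    multicenter research studies such as blood-donor serosurveillance
    cohorts. A single project-wide YAML configuration file carries the
    study's data dictionaries, quality-control policy, lookup tables,
    per-organization intake buckets and report specifications; the code
    stays study-agnostic. Modules cover dictionary-driven validation of
    delimited submissions with itemized issue reports, an embedded
    relational study store whose materialized constraints act as a
    redundant quality-control line, an upload/download/archive bucket
    intake workflow with pluggable notification sinks, a long-format
    consent-gated survey store with cross-round question equivalency,
    configuration-driven reporting, privacy-minimization transforms, and
    a seedable simulator of a complete multicenter study with controlled
    error injection and a ground-truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
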