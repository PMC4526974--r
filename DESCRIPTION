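Package: pmlog
Title: Session Analysis of PubMed-Style Search Query Logs
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing full-day PubMed-style query logs: record
    cleaning with an auditable report, approximate automatic term mapping and
    query-intent categorization (informational, navigational, mixed) driven by
    a configurable search-field-tag lexicon with fuzzy tag resolution,
    session segmentation by a temporal window plus intent shifts, session- and
    user-level classification of search expertise from system-function usage
    (field tags, MeSH terms, truncation, search-history references), and
    descriptive session-length statistics including decrease rates from the
    length-1 baseline. A seeded synthetic-log generator with ground-truth
    labels makes every stage testable without access to production log files.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
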