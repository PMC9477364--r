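Package: chronoage
Title: Chronometric Age Extension Tools for Darwin Core Occurrence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for publishing, validating and querying chronometric age
    information attached to biodiversity occurrence records via the ratified
    ChronometricAge extension to Darwin Core.  Provides the term registry for
    the extension vocabulary, a validated record model with quality flags,
    normalization of heterogeneous age reference systems (BP, BCE/CE, ka, Ma,
    Ga) onto a canonical calendar-years-before-1950 axis with interval
    queries, Darwin Core Archive reading and writing with many-to-one
    extension rows, a JSON dialect for embedding ages in dwc:dynamicProperties,
    a field scanner that audits legacy occurrence corpora for chronometric
    content hiding in non-chronometric fields, and deterministic synthetic
    fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
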