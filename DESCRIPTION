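Package: voltfair
Title: FAIR Data Workflows for Cyclic Voltammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning vendor potentiostat output from cyclic
    voltammetry (CV) measurements into open, standardized, richly annotated
    datasets. Provides readers for tagged-text and CSV instrument dialects,
    declarative conversion profiles that map device files to per-cycle
    JCAMP-DX documents and a community-style CV metadata scheme, BagIt
    packaging with sha256/sha512 fixity manifests, peak picking and
    standardized descriptors (half-wave potential E1/2, peak separation
    dEp, peak-current ratio ipa/ipc with Nicholson switching-current
    correction), spreadsheet and archive exports, a folder watcher for
    unattended ingestion, and a finite-difference simulator of reversible
    voltammograms used to generate test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    zip,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    png
Config/testthat/edition: 3
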