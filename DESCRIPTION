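Package: keytables
Title: Reconstruction and Scoring of Key-Resource Tables from PDF Character Boxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebuilds STAR*Methods-style key-resource tables (reagents,
    antibodies, organisms, software, RRIDs) from PDF-derived character
    bounding boxes and table-detection bounding boxes. Provides geometric
    column/row range estimation and heuristic row canonicalization, a
    character-level generative transformer language model of table cells
    fine-tuned into a row-merge classifier that repairs row
    over-segmentation caused by overflowing cells, an OCR-based variant
    behind a pluggable engine, a two-level stacked page classifier that
    flags resource-table pages, a synthetic table generator with a
    simulated cell-overflow training-data scheme, and the GriTS family of
    grid table similarity metrics (content, topology, location) with an
    exhaustive-enumeration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
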