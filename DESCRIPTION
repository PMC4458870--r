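Package: muscscreen
Title: Proteome-Guided Arrayed shRNA Screen Analysis for Muscle Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proteome-driven arrayed RNA-interference
    screens in muscle stem (satellite) cells. Derives a stem-cell-specific
    proteome from label-free protein-group tables by identification
    filtering, fraction subtraction and intensity gating; models 384-well
    knockdown screen plates with a Pax7+/DAPI+ nucleus-ratio read-out;
    applies Z'-factor plate quality control and per-plate empty-vector
    normalization; and calls gene-level hits by percentile thresholds with
    multi-shRNA consensus and opposing-phenotype subtraction. Ships a
    seeded synthetic-data generator (screens, proteome tables and
    two-channel well images) carrying planted ground truth so every stage
    is testable without raw data, plus TSV/spreadsheet readers, a report
    writer and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
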