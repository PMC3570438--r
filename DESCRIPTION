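Package: splprofiler
Title: Profiling FDA Structured Product Labels with NDF-RT and RxNorm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for crosswalking FDA Structured Product Labeling (SPL)
    drug labels to the standard drug terminologies NDF-RT and RxNorm.
    Parses External Pharmacologic Class (EPC) indexing SPL documents in
    XML, NDF-RT concept serializations (tabular or triples), and the
    RxNorm Rich Release Format files RXNCONSO.RRF and RXNSAT.RRF;
    classifies labels by EPC class, NDF-RT category (VA Product,
    Chemical/Ingredient, EPC) and RxNorm term type (TTY); computes
    per-category coverage tables with exact half-up rounding; builds and
    exports a directed drug/drug-class network in SIF and GraphML for
    Cytoscape. Includes a deterministic synthetic-fixture generator that
    emits internally consistent SPL/NDF-RT/RxNorm corpora together with
    their ground-truth profile tables, and a command-line entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    xml2,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
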