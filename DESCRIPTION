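Package: seqfab
Title: Workflow Engine for Sanger DNA Sequencing Facilities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A headless, scriptable laboratory information management
    workflow for Sanger DNA sequencing core facilities. Takes customer
    orders (entered programmatically or from CSV/XLSX sample sheets),
    validates concentrations and volumes against configurable limits,
    pools orders into 96-well plate runs, computes per-well liquid
    recipes, emits worklists for liquid-handling robots and the
    instrument set-up sheet for the sequencer, ingests sequencer output
    from ZIP archives, scores and trims the resulting reads, and serves
    results back per order with group-based access control, an
    append-only event log, and a deterministic synthetic-data generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    xml2,
    readxl,
    Biostrings,
    utils,
    stats,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
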