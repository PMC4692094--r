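Package: mzqsrm
Title: Selected Reaction Monitoring Data in the mzQuantML Standard
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Read, write, build and validate mzQuantML (version 1.0.1)
    documents for selected reaction monitoring (SRM) experiments. Provides
    an in-memory data model for transitions, feature quantification layers
    and peptide/protein consensus objects; an importer for Skyline-style
    SRM report CSV files; transition-to-peptide-to-protein aggregation with
    light/heavy isotope ratio support; a semantic validator enforcing the
    SRM-specific controlled-vocabulary rules; and a seedable generator of
    synthetic SRM experiments with known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
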