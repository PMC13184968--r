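Package: fermeta
Title: Schema Engine for Fermentation Minimum-Information Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An executable schema engine for minimum-information metadata
    models used in industrial-biotechnology fermentation (MIFE for
    experiments, MIFD for devices). Reads schema workbooks written in a
    spreadsheet dialect (one sheet of hierarchical metadata levels plus one
    sheet of term definitions per level), compiles them into a
    LinkML-dialect YAML schema document, generates fill-in Excel metadata
    templates, parses and validates filled templates with strictness-tiered
    findings (mandatory/recommended/optional), exports validated metadata
    to RDF (Turtle or N-Triples) with CURIE expansion, and constructs a
    Common Provenance Model backbone of main activities with backward and
    forward connectors. Includes a deterministic fixture generator so the
    whole pipeline is testable offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    readxl,
    tibble,
    jsonlite,
    yaml,
    zip,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
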