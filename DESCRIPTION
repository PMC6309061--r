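Package: meshrank
Title: Disease Prioritization from MeSH-Annotated Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a publication-to-disease link table from MEDLINE records
    annotated with MeSH (Medical Subject Headings) disease descriptors,
    prioritizes diseases for an arbitrary PubMed query by the upper tail of
    the hypergeometric distribution computed in log space, and evaluates
    ranked disease lists against curated gold standards with standard
    information-retrieval metrics (precision, recall, F-measure, average
    precision, MAP, precision at k). Includes an offline fixture retrieval
    backend, a synthetic-corpus generator with planted query-specific
    enrichment for end-to-end testing without network access, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
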