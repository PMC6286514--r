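Package: termnet
Title: Gene Ontology Enrichment and Annotation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline Gene Ontology (GO) analysis engine that resolves submitted
    gene or protein identifiers to species-specific primary IDs, tests GO terms
    for over-representation with the one-sided hypergeometric (Fisher exact)
    test under Benjamini-Hochberg FDR control against a configurable background,
    or maps genes onto a GO slim subset, and renders the result as a reduced
    directed gene-term graph (transitive reduction over the term hierarchy,
    most-specific gene attachment, orphan retention). Reads OBO ontology files
    and GAF association files, and exports CSV tables, indented text hierarchies,
    Cytoscape JSON (.cyjs) networks and ID-mapping tables. Includes a synthetic
    fixture generator (ontologies, annotation corpora, mapping and expression
    tables, spiked gene lists) so the full pipeline is testable without any
    download, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
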