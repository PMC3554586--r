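Package: seedkb
Title: Ontology-Driven Data Integration into Federated RDF Knowledge Bases
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A declarative, ontology-driven data-integration engine for
    biomedical knowledge bases. Heterogeneous sources (CSV files, XML
    documents, SQL query results and SPARQL endpoints) are triplified into
    an RDF knowledge base organized as an Entity-Concept-Item tree, driven
    entirely by a setup graph that wires concepts to resources, selectors
    and bridges. Three integration methods (cache, complete, map) create
    items, append properties to existing items, or link items with object
    properties. The resulting knowledge base is exposed through a
    triple-pattern API, a SPARQL engine with multi-format results,
    per-resource LinkedData views, and a federation layer that joins
    SERVICE clauses across several knowledge bases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Collate:
    'utils.R'
    'vocabulary.R'
    'AllClasses.R'
    'KnowledgeBase.R'
    'access-api.R'
    'connectors.R'
    'fixtures.R'
    'integration.R'
    'rdf-io.R'
    'seed-model.R'
    'sparql.R'
RoxygenNote: 7.3.3
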