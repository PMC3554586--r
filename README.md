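# seedkb

**Declarative, ontology-driven data integration into federated RDF
knowledge bases.**

Biomedical data relevant to a single question — which genes underlie a
rare disease, which proteins they encode, which structures, motifs and
publications describe those proteins — is scattered across CSV exports,
XML web services, relational databases and SPARQL endpoints, each with its
own data model and none with shared semantics. `seedkb` is for developers
of niche biomedical information systems (rare-disease portals,
gene/protein resource aggregators) who want to stand up such a *knowledge
seed* — one self-contained RDF knowledge base plus its query surface —
from a purely declarative configuration, without writing per-source ETL
code.

## The model

A seed's content is organized as a three-level tree described by a small
internal ontology (prefix `seed:`):

```
Seed ─includes→ Entity ─isEntityOf→ Concept ─isConceptOf→ Item
                (Protein)           (UniProt)             (uniprot_P51587)
```

* **Entity** — a broad category (*Gene*, *Protein*, *Disease*).
* **Concept** — a source-specific data type (*HGNC*, *UniProt*, *OMIM*),
  belonging to exactly one entity (`seed:hasConcept` /
  `seed:isConceptOf`; all structural predicates are materialized in both
  directions at write time, so plain triple-pattern queries see either
  side).
* **Item** — one record of a concept, with URI
  `<namespace><lowercase(concept)>_<encoded(identifier)>`, e.g.
  `:uniprot_P51587` or `:hgnc_HGNC%3A1101`.

Integration is driven by two artifacts: `config.js` (instance name,
namespace, prefixes) and a setup graph (`setup.rdf`, RDF/XML or Turtle)
that attaches **Resources** to concepts. A resource names its connector
kind (CSV, XML, SQL, SPARQL), its endpoint URI (optionally containing the
literal token `#replace#`), an integration **method**, and a set of
**selectors** — data locations (a 0-based column index, an XPath
expression, a result-column name, a query variable) paired with the RDF
predicates their values populate. One selector per resource is the *key
selector* supplying the item identifier (by default the one mapping
`dc:identifier`).

The three integration methods are:

| method     | effect                                                                 |
|------------|------------------------------------------------------------------------|
| `cache`    | create new items from scratch, one per distinct key value              |
| `complete` | append properties to the existing items of the concept named by `seed:extends` (per-item fetch via `#replace#`, or one fetch joined by key equality) |
| `map`      | add `seed:isAssociatedTo` links (both directions) between existing items of two concepts |

Each record first becomes a model-independent *item map* — the
cross-product of every selector's values and properties — and is then
triplified: `rdf:type seed:Item`, `seed:hasConcept`, an `rdfs:label`
(defaulting to *concept label + identifier* unless a selector maps the
label explicitly), and one statement per (predicate, value) pair. The
store has set semantics, so rebuilding is idempotent.

The built knowledge base is exposed four ways, mirroring the route grammar
`/api/triple/<sub>/<pred>/<obj>/<format>`:

* `getTriple(sub, pred, obj, format, kb)` — triple patterns with
  positional wildcards (`sub|s`, `pred|p`, `obj|o`) and csv/js/xml/rdf/html
  output;
* `sparqlEndpoint(query, output, kb)` — read-only SPARQL
  (SELECT/ASK/CONSTRUCT/DESCRIBE) with format negotiation;
* `linkedDataView(localname, mode, kb, ns)` — a dereferenceable
  per-resource document (RDF or HTML);
* `federatedQuery(query, registry)` — queries whose `SERVICE` clauses are
  resolved against a registry of endpoints and joined in clause order,
  turning several seeds into one *knowledge garden*.

## Worked example

The package ships a deterministic fixture generator that emulates a
rare-disease portal: diseases fan out to genes, proteins, structures,
motifs and literature across all four connector kinds and all three
methods.

```r
library(seedkb)
spec   <- fixtureSpec(randomSeed = 1, nDiseases = 4L, outputDir = tempfile())
bundle <- generateFixtureSeed(spec)
model  <- parseSetup(paste(readLines(bundle$setupPath), collapse = "\n"),
                     parseSeedConfig(bundle$configPath))
report <- buildSeed(model, registry = bundle$registry)
report
```

```
BuildReport: 14 resources in order [OMIM, HGNC, HGNC_names, UniProt, UniProt2HGNC,
UniProt_details, PDB, PROSITE, InterPro, PharmGKB, Entrez, PubMed, MeSH, Orphanet]
          resource   method records items statements links skips failed error
1             OMIM    cache       7     4         27     0     0  FALSE      
2             HGNC    cache       7     7         35     0     0  FALSE      
3       HGNC_names complete       7     0          7     0     0  FALSE      
4          UniProt    cache      10    10         60     0     0  FALSE      
5     UniProt2HGNC      map      10     0         20    10     0  FALSE      
...
```

Reading the report: the OMIM morbid-map-style CSV had 7 rows describing 4
distinct diseases (duplicate keys merge into one item each), the SQL
connector cached 10 proteins, the map resource created 10
protein-to-gene `isAssociatedTo` links (20 statements — both directions),
and the per-protein `#replace#` complete appended exactly one title per
protein. The store ends at 833 statements
(`kbSize(attr(report, "kb"))`), and every count is predicted exactly by
the bundle's closed-form manifest (`bundle$manifest`).

Querying one protein through the triple-pattern API:

```r
kb <- attr(report, "kb")
cat(getTriple("kb:uniprot_P73974", "p", "o", "csv", kb))
```

```
"subject",...,"predicate",...,"object",...
"http://localhost/seed/uniprot_P73974",..."...rdf-syntax-ns#type",...,"http://seedkb.org/ontology/Item",...
"http://localhost/seed/uniprot_P73974",..."...hasConcept",...,"http://localhost/seed/concept_UniProt",...
"http://localhost/seed/uniprot_P73974",..."...#label",...,"UniProt P73974",...
"http://localhost/seed/uniprot_P73974",..."...identifier",...,"P73974",...
"http://localhost/seed/uniprot_P73974",..."...isAssociatedTo",...,"http://localhost/seed/hgnc_HGNC%3A6519",...
```

The same statement set is returned by the SPARQL endpoint
(`SELECT ?p ?o WHERE { kb:uniprot_P73974 ?p ?o }`) and by
`linkedDataView("uniprot_P73974", "rdf", kb, ns)` — the three interfaces
are interchangeable views of the store.

A shell entry point wrapping these functions is installed at
`inst/scripts/seed.R`:

```sh
Rscript seed.R fixtures --seed 1 --out fx
Rscript seed.R build    --config fx/config.js --setup fx/setup.rdf --out kb.ttl
Rscript seed.R query    --kb kb.ttl --sparql query.rq --output csv
```

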