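---
title: "Knowledge seeding: declarative triplification of heterogeneous biomedical sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge seeding: declarative triplification of heterogeneous biomedical sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedkb)
```

## The integration model

`seedkb` treats data integration as a declarative mapping problem rather
than a programming one. The target schema is a fixed three-level tree —
Entity → Concept → Item — expressed in a small internal ontology, and the
*only* thing a user writes is configuration: which concepts exist, which
external resource feeds each one, and which locations in that resource map
onto which RDF predicates. The engine owns everything between a source
byte stream and the triple store.

The assumptions behind this model are worth making explicit:

* **Every source is record-shaped.** A CSV row, an XML record node, a SQL
  result row and a SPARQL solution are all treated as the same thing: a
  map from selector handles to lists of string values (with term kinds
  retained for SPARQL, whose bindings already carry semantics). This
  *record set* is the package's model-independent intermediate form; the
  connector-independence tests assert that the same logical table yields
  value-identical record sets through all four connectors.
* **Each record describes (part of) one item**, identified by the key
  selector's value. Records sharing a key merge into one item under set
  semantics; there is no notion of record order mattering.
* **No reasoning.** Structural predicates that come in inverse pairs
  (`includes`/`isIncludedIn`, `isEntityOf`/`hasEntity`,
  `isConceptOf`/`hasConcept`, resource/bridge attachment, and the
  symmetric `isAssociatedTo`) are materialized in both directions when
  statements are written, so a plain triple-pattern API observes both
  sides without an entailment regime. The cost — a handful of extra
  statements per item — buys predictable query behaviour.

## Parameters that matter

* **`method`** (`cache` | `complete` | `map`, default `cache`): the
  integration strategy. `cache` mints new items; `complete` appends to
  the items of the concept named by `seed:extends`; `map` only adds
  `isAssociatedTo` links between existing items, skipping (and counting)
  pairs whose endpoint items are absent.
* **`seed:order`** (integer, default 0): tie-break priority within the
  dependency ordering. The hard constraint is topological — a resource
  that extends concept *C* runs after every resource attached to *C* —
  and ties resolve by `(order, key)` ascending so builds are
  deterministic. Cycles are refused with the cycle members listed.
* **Key-selector designation**: a selector is the key selector iff its
  `seed:isKey` flag is set; when no flag is present the selector mapping
  `dc:identifier` is promoted. This default was chosen because in
  practice the identifier column *is* the primary key of the record, and
  it keeps minimal configurations free of boilerplate. Exactly one key
  selector per resource is enforced by validation.
* **Item labeling**: `rdfs:label` defaults to *concept label +
  identifier* (`"UniProt P51587"`); a selector mapping `rdfs:label`
  explicitly suppresses the default for that item. The original system
  mentions per-item labeling rules without defining them; this rule is
  the simplest one that leaves every item with a human-readable label.
* **Literal vs URI objects**: values selected from CSV/XML/SQL become
  plain literals unless the target predicate is registered as an object
  property in the vocabulary; SPARQL-selected values keep their original
  term kind. Non-semantic formats genuinely carry no term-kind
  information, so the predicate is the only place the distinction can
  live.
* **CSV dialect**: comma-separated, double-quote quoting with `""`
  escapes, first row treated as a header unless `seed:header` is
  `"false"` (gene-list exports ship headers). Rows too narrow for a
  selector's column index are skipped and reported — the skip report plus
  the record count always reconstructs the source row count.
* **XML record path**: per-field XPath selectors need a definition of
  "one record"; the open property `seed:recordPath` supplies it,
  defaulting to the document root (a single record). Selector XPaths are
  evaluated relative to each record node, multi-matches yielding multiple
  values in document order.
* **`#replace#`**: the single substitution token used uniformly in
  resource endpoints (per-item completes), and bridge URL patterns. A
  complete resource *without* the token is fetched once and joined to
  items by key-selector equality — the natural reading of "one file
  completes many items".

## URI minting and degenerate inputs

Item URIs are `namespace + lowercase(concept) + "_" + identifier` with
the identifier percent-encoded per the generic URI syntax
(`HGNC:1101 → hgnc_HGNC%3A1101`). Encoding makes minting injective in
practice, but two distinct raw identifiers can still collide after
encoding (`"A:1"` vs `"A%3A1"`); the build refuses such a configuration,
naming both identifiers, rather than silently merging records. Empty key
values never mint (counted as skips); empty sources build zero items
without error; resource-level failures (unreachable endpoint, bad query)
mark that resource failed in the report and the build continues —
failure isolation keeps one broken upstream from voiding a whole seed,
while `buildFailed()` still exposes the overall status.

## The query surface

The SPARQL engine implements the subset this architecture needs: SELECT /
ASK / CONSTRUCT / DESCRIBE over basic graph patterns with `OPTIONAL`,
`FILTER` (`=`, `!=`, `regex`, `bound`), `DISTINCT`, `ORDER BY`,
`LIMIT/OFFSET`, and `SERVICE`. Update forms are rejected before
execution. Federation is executed by nested binding propagation in
SERVICE-clause order — each clause is evaluated against its registered
endpoint and joined on shared variables — which is deliberately
non-optimizing: at the scale of a handful of seeds it is exact and easy
to audit, and the suite verifies that federated execution equals running
the de-federated pattern over the union of the endpoint graphs.

Endpoints are in-process objects: a registry maps endpoint URIs to
knowledge bases, and SERVICE clauses, SPARQL connectors and the
federation tests all resolve through it. An unregistered endpoint is an
error naming the URI — never a silent partial result. The same functions
back the HTTP-style route grammar (`/api/triple/...`, `/sparql`,
`/resource/{localname}`), so mounting them behind an actual web server is
a deployment detail, not a package concern. When the `output` parameter
is absent the SPARQL endpoint returns SPARQL-results XML; the original
interface description names the parameter but not its default, and XML is
the most widely parsed of the standard result formats.

Two serialization choices are worth noting. The `js` token emits standard
SPARQL-results JSON (for both SELECT results and triple patterns), since
"JSON" alone underdetermines a schema. The CSV rendering of results
appends per-variable kind/lang/datatype columns; plain SPARQL CSV is
lossy, and the format round-trip property (csv, js and xml outputs
deserialize to the same statement set) requires losslessness.

## What the fixture generator emulates — and what it does not

`generateFixtureSeed()` builds an offline bundle shaped like a
rare-disease portal's integration graph: OMIM-style disease records fan
out to genes (HGNC-style, with colon-bearing identifiers to exercise URI
encoding), proteins (UniProt-style accessions, served from an embedded
SQLite database), per-protein cross-references (PDB / PROSITE / InterPro /
PharmGKB, served as XML), gene mappings behind an auxiliary SPARQL
endpoint (Entrez-style), literature (PubMed-style) and terminology (MeSH,
Orphanet). Eleven concepts across all four connector kinds, exercising
cache, complete (both per-item and join forms) and map.

Default study conditions: 6 diseases, 1–3 genes per disease, 1–2 proteins
per gene, 1–3 cross-references per protein per target, 1–2 publications
per gene — branching factors typical of a small rare-disease neighborhood
and large enough that every code path (duplicate keys, multi-value
selectors, percent-encoded identifiers) occurs. Everything derives from
one integer seed; the same spec yields byte-identical files, and a
manifest predicts every item and statement count by closed-form
arithmetic, giving the engine an exact external target.

What the fixtures do *not* emulate: real-world identifier cross-linking
noise (dangling references occur only where tests construct them),
schema drift and malformed records, authentication, rate limits and
network failure modes, and source volumes beyond a few hundred records.
Passing tests therefore demonstrate the correctness of the mapping and
counting semantics, not robustness against the full pathology of live
biomedical services.

The federation fixture reproduces a three-service topology — gene labels
on one endpoint, gene→protein links on a second, protein→structure and
protein→term links on a third — with distinct predicates per endpoint so
that the union-graph comparison is well-defined.

## Problem sizes and verification scale

The test suite runs entirely at desk scale: bundles of 2–6 diseases
(roughly 800–1100 statements), brute-force oracles on ≤ 100-row sources,
and exhaustive permutation checks of the dependency ordering on graphs of
≤ 6 resources. These sizes were chosen so every oracle can be exact —
permutation enumeration, explicit cross-product counting, set comparison
of full statement tables — rather than sampled.

## Known limitations

* The RDF readers/writers cover the dialect the engine emits and the
  setup files use: no blank nodes, collections, or reification. A parse
  error, not silent acceptance, greets anything outside that subset.
* The SPARQL subset omits `UNION`, property paths, aggregation and
  subqueries; `FILTER` supports equality, inequality and regex only.
* The SQL connector targets the embedded SQLite engine through connection
  URIs of the form `sqlite:///path`; other relational backends would need
  their own bridge.
* complete appends literal and URI properties to existing items but never
  creates items; inbound references to a LinkedData resource are exposed
  through the object-bound triple pattern rather than the subject view.
* Federation is exact but unoptimized; queries spanning many large
  endpoints would need join reordering the engine does not attempt.
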