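## S4 classes for the configuration model, the knowledge base and the
## intermediate containers of the integration pipeline.

#' @include vocabulary.R utils.R
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Seed configuration (instance properties)
#'
#' Parsed form of \code{config.js}: application name, version, description,
#' deployment environment, the instance base namespace, the CURIE prefix
#' map and the list of imported ontology documents.
#'
#' @slot name,version,description,environment Single strings.
#' @slot baseNamespace Absolute URI; minted item/concept URIs live under it.
#' @slot prefixes Named character vector prefix -> namespace URI.
#' @slot ontologyImports Character vector of ontology document URIs.
#' @exportClass SeedConfig
setClass("SeedConfig",
  representation(name = "character", version = "character",
                 description = "character", environment = "character",
                 baseNamespace = "character", prefixes = "character",
                 ontologyImports = "character"),
  prototype(name = "", version = "0", description = "", environment = "dev",
            baseNamespace = "http://localhost/seed/", prefixes = character(),
            ontologyImports = character()))

setValidity("SeedConfig", function(object) {
  msgs <- character()
  if (!isString(object@name) || !nzchar(object@name))
    msgs <- c(msgs, "name must be a nonempty string")
  if (!isAbsoluteURI(object@baseNamespace))
    msgs <- c(msgs, "baseNamespace must be an absolute URI")
  bad <- object@prefixes[!isAbsoluteURI(object@prefixes)]
  if (length(bad))
    msgs <- c(msgs, paste0("prefix does not map to an absolute URI: ",
                           paste(names(bad), collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Selector: one data location mapped to RDF predicates
#'
#' The query dialect depends on the owning resource's connector kind:
#' a 0-based column index (CSV), an XPath expression (XML), a result-column
#' name (SQL) or a variable name (SPARQL). Values found at the location are
#' asserted under every predicate in \code{properties}. The key selector
#' supplies the item identifier used to mint the subject URI.
#'
#' @slot key Selector handle (unique within its resource).
#' @slot query Location expression in the connector's dialect.
#' @slot properties Predicate CURIEs populated by this selector.
#' @slot isKey Does this selector yield the item identifier?
#' @exportClass Selector
setClass("Selector",
  representation(key = "character", query = "character",
                 properties = "character", isKey = "logical"),
  prototype(isKey = FALSE))

setValidity("Selector", function(object) {
  msgs <- character()
  if (!isString(object@key) || !nzchar(object@key))
    msgs <- c(msgs, "selector key must be nonempty")
  if (!isString(object@query))
    msgs <- c(msgs, "selector query must be a single string")
  if (!length(object@properties))
    msgs <- c(msgs, "selector must map at least one property")
  if (length(msgs)) msgs else TRUE
})

#' Resource definition: one external source
#'
#' @slot key Resource handle, unique within the model.
#' @slot kind Connector kind: csv, xml, sql or sparql.
#' @slot method Integration method: cache (create items), complete (append
#'   properties to existing items) or map (link existing items).
#' @slot endpoint Source URI template; may contain the literal token
#'   \code{#replace#} substituted per item.
#' @slot connectorHint dc:publisher value naming the connector.
#' @slot conceptKey Concept populated (cache) or driving (complete/map).
#' @slot extendsKey Concept whose items are enriched; required for
#'   complete and map, absent (NA) for cache.
#' @slot selectors List of \linkS4class{Selector}.
#' @slot order Integer priority for tie-breaking the build order.
#' @slot extras Open property map (named list of character vectors);
#'   unknown setup predicates are preserved here verbatim.
#' @exportClass ResourceDef
setClass("ResourceDef",
  representation(key = "character", kind = "character", method = "character",
                 endpoint = "character", connectorHint = "character",
                 conceptKey = "character", extendsKey = "character",
                 selectors = "list", order = "integer", extras = "list"),
  prototype(method = "cache", endpoint = "", connectorHint = "",
            extendsKey = NA_character_, selectors = list(), order = 0L,
            extras = list()))

setValidity("ResourceDef", function(object) {
  msgs <- character()
  if (!object@kind %in% names(SELECTOR_CLASSES))
    msgs <- c(msgs, sprintf("unknown connector kind '%s'", object@kind))
  if (!object@method %in% c("cache", "complete", "map"))
    msgs <- c(msgs, sprintf("unknown method '%s'", object@method))
  if (length(msgs)) msgs else TRUE
})

#' Entity definition ("umbrella" category grouping concepts)
#' @slot key Entity handle.
#' @slot label Human-readable label.
#' @slot conceptKeys Keys of the concepts grouped under this entity.
#' @exportClass EntityDef
setClass("EntityDef",
  representation(key = "character", label = "character",
                 conceptKeys = "character"),
  prototype(label = "", conceptKeys = character()))

#' Concept definition (source-specific data type)
#' @slot key Concept handle.
#' @slot entityKey The unique owning entity.
#' @slot label Human-readable label (used in item labeling).
#' @slot resourceRefs,bridgeRefs Keys of attached resources / bridges.
#' @exportClass ConceptDef
setClass("ConceptDef",
  representation(key = "character", entityKey = "character",
                 label = "character", resourceRefs = "character",
                 bridgeRefs = "character"),
  prototype(label = "", resourceRefs = character(), bridgeRefs = character()))

#' Bridge definition (outbound URL / visualization template)
#' @slot key Bridge handle.
#' @slot conceptKey Owning concept.
#' @slot pattern Template with zero or more \code{#replace#} tokens.
#' @slot extraProperties Open predicate -> literal map.
#' @exportClass BridgeDef
setClass("BridgeDef",
  representation(key = "character", conceptKey = "character",
                 pattern = "character", extraProperties = "list"),
  prototype(pattern = "", extraProperties = list()))

#' The parsed seed model
#'
#' The full configuration tree: instance config plus entities, concepts,
#' resources and bridges keyed by handle, and any extra statements from the
#' setup graph preserved verbatim.
#'
#' @slot config A \linkS4class{SeedConfig}.
#' @slot entities,concepts,resources,bridges Named lists of definitions.
#' @slot extras data.frame of preserved unknown statements.
#' @exportClass SeedModel
setClass("SeedModel",
  representation(config = "SeedConfig", entities = "list", concepts = "list",
                 resources = "list", bridges = "list", extras = "data.frame"),
  prototype(entities = list(), concepts = list(), resources = list(),
            bridges = list(), extras = emptyStatements()))

#' RDF knowledge base (triple store)
#'
#' A named-graph-capable triple store with set semantics: inserting a
#' duplicate statement leaves the store unchanged. Structural predicates
#' with registered inverses are materialized in both directions at write
#' time. The store is a reference object: all methods that add statements
#' mutate it in place, as triple stores in this domain universally do.
#'
#' @slot ptr Environment holding the statement table and the prefix map.
#' @seealso \code{\link{KnowledgeBase}} constructor,
#'   \code{\link{addStatements}}, \code{\link{matchTriples}}
#' @exportClass KnowledgeBase
setClass("KnowledgeBase", representation(ptr = "environment"))

#' Fetch specification (resolved source address)
#' @slot uri Resolved URI (no residual \code{#replace#} token).
#' @slot kind Connector kind.
#' @slot queryText SQL/SPARQL query string where applicable.
#' @exportClass FetchSpec
setClass("FetchSpec",
  representation(uri = "character", kind = "character",
                 queryText = "character"),
  prototype(queryText = NA_character_))

setValidity("FetchSpec", function(object) {
  if (grepl("#replace#", object@uri, fixed = TRUE))
    return("uri contains a residual #replace# token")
  if (!object@kind %in% names(SELECTOR_CLASSES))
    return(sprintf("unknown connector kind '%s'", object@kind))
  TRUE
})

#' Record set: the model-independent intermediate format
#'
#' One record per source row / XML record node / SQL row / SPARQL solution.
#' Each record maps every selector handle of the driving resource to a
#' character vector of values (possibly empty), with term kinds retained in
#' a parallel structure (\code{"uri"} or \code{"literal"}).
#'
#' @slot records List of records (named lists of character vectors).
#' @slot kinds Parallel list of term-kind vectors.
#' @slot sourceUri URI actually fetched.
#' @slot skips data.frame(row, reason) of skipped source units.
#' @exportClass RecordSet
setClass("RecordSet",
  representation(records = "list", kinds = "list", sourceUri = "character",
                 skips = "data.frame"),
  prototype(records = list(), kinds = list(), sourceUri = "",
            skips = data.frame(row = integer(), reason = character(),
                               stringsAsFactors = FALSE)))

#' Item map: the per-item network produced before triplification
#'
#' @slot identifier Item identifier from the key selector.
#' @slot conceptKey Owning concept.
#' @slot properties data.frame(predicate, value, kind): the multimap of
#'   predicate CURIEs to (value, term-kind) pairs.
#' @exportClass ItemMap
setClass("ItemMap",
  representation(identifier = "character", conceptKey = "character",
                 properties = "data.frame"))

setValidity("ItemMap", function(object) {
  if (!isString(object@identifier) || !nzchar(object@identifier))
    return("item identifier must be nonempty")
  TRUE
})

#' Build report
#'
#' Per-resource accounting of a knowledge-base build: records seen, items
#' created, statements added, links created, skips and errors, plus the
#' dependency order that was used.
#'
#' @slot resources data.frame with one row per executed resource.
#' @slot ordering Resource keys in execution order.
#' @exportClass BuildReport
setClass("BuildReport",
  representation(resources = "data.frame", ordering = "character"))

#' Fixture specification
#'
#' Deterministic generator settings for the offline rare-disease-portal
#' style fixture bundle (sources, setup graph, embedded database, mapping
#' lists and an expected-count manifest). The same spec always produces
#' byte-identical files.
#'
#' @slot randomSeed Integer seed driving every random draw.
#' @slot nDiseases Number of disease records.
#' @slot genesPerDisease,proteinsPerGene,xrefsPerProtein Integer ranges
#'   (length-2 min/max) for the branching factors of the fixture graph.
#' @slot conceptList Ordered concept names in the bundle.
#' @slot outputDir Directory the bundle is written into.
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(randomSeed = "integer", nDiseases = "integer",
                 genesPerDisease = "integer", proteinsPerGene = "integer",
                 xrefsPerProtein = "integer", conceptList = "character",
                 outputDir = "character"),
  prototype(randomSeed = 1L, nDiseases = 6L, genesPerDisease = c(1L, 3L),
            proteinsPerGene = c(1L, 2L), xrefsPerProtein = c(1L, 3L),
            conceptList = character(), outputDir = ""))

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  for (nm in c("nDiseases", "genesPerDisease", "proteinsPerGene",
               "xrefsPerProtein")) {
    v <- slot(object, nm)
    if (any(v < 0L)) msgs <- c(msgs, paste0(nm, " must be >= 0"))
  }
  if (length(msgs)) msgs else TRUE
})
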