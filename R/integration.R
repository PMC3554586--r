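## The integration engine: turn RecordSets into triples — item-URI minting,
## the per-item abstraction map, and the cache / complete / map methods.

#' Mint an item URI
#'
#' \code{namespace + lowercase(conceptKey) + "_" + encoded(identifier)},
#' with URI-reserved characters in the identifier percent-encoded.
#' Deterministic, and injective for distinct (concept, id) pairs up to the
#' collision check performed at build time.
#'
#' @param conceptKey Concept handle, e.g. "UniProt".
#' @param itemId Item identifier, e.g. "P51587".
#' @param namespace Instance base namespace.
#' @return Absolute URI string.
#' @examples
#' mintItemUri("UniProt", "P51587", "http://localhost/seed/")
#' @export
mintItemUri <- function(conceptKey, itemId, namespace) {
  if (!all(nzchar(itemId)))
    skbStop("seedkb_build_error", "item identifier must be nonempty")
  paste0(namespace, tolower(conceptKey), "_", percentEncode(itemId))
}

conceptURI <- function(model, conceptKey)
  paste0(model@config@baseNamespace, "concept_", conceptKey)

## Two distinct identifiers sanitizing onto one URI is a configuration the
## build must refuse rather than silently merge.
checkMintCollisions <- function(conceptKey, ids, namespace) {
  ids <- unique(ids)
  uris <- mintItemUri(conceptKey, ids, namespace)
  dup <- duplicated(uris)
  if (any(dup)) {
    clash <- uris[dup][1L]
    both <- ids[uris == clash]
    skbStop("seedkb_build_error",
            sprintf("identifier sanitization collision in concept '%s': '%s' and '%s' both map to <%s>",
                    conceptKey, both[1L], both[2L], clash))
  }
  invisible(TRUE)
}

#' Build item maps from a record set
#'
#' Generates the model-independent per-item network: one
#' \linkS4class{ItemMap} per record with a nonempty key value, where every
#' selector contributes the cross-product of its properties and its values
#' to the predicate multimap. Records with an empty key are counted as
#' skips (attribute \code{"skips"} on the result), never silently dropped.
#'
#' @param records A \linkS4class{RecordSet}.
#' @param resource The driving \linkS4class{ResourceDef} (must have a key
#'   selector).
#' @return List of \linkS4class{ItemMap} with integer attribute "skips".
#' @export
makeItemMaps <- function(records, resource) {
  keyIdx <- which(vapply(resource@selectors, slot, TRUE, "isKey"))
  if (length(keyIdx) != 1L)
    skbStop("seedkb_config_error",
            sprintf("resource '%s' needs exactly one key selector", resource@key))
  keyHandle <- resource@selectors[[keyIdx]]@key
  handleProps <- stats::setNames(
    lapply(resource@selectors, slot, "properties"),
    vapply(resource@selectors, slot, "", "key"))
  maps <- list(); skips <- 0L
  for (i in seq_along(records@records)) {
    rec <- records@records[[i]]
    knd <- if (length(records@kinds) >= i) records@kinds[[i]] else list()
    keyVals <- rec[[keyHandle]]
    if (!length(keyVals) || !nzchar(keyVals[[1L]])) { skips <- skips + 1L; next }
    rows <- list()
    for (h in names(handleProps)) {
      vals <- rec[[h]] %||% character()
      if (!length(vals)) next
      kinds <- knd[[h]] %||% rep("literal", length(vals))
      if (length(kinds) != length(vals)) kinds <- rep("literal", length(vals))
      for (p in handleProps[[h]])
        rows[[length(rows) + 1L]] <- data.frame(
          predicate = p, value = vals, kind = kinds, stringsAsFactors = FALSE)
    }
    props <- if (length(rows)) do.call(rbind, rows)
             else data.frame(predicate = character(), value = character(),
                             kind = character(), stringsAsFactors = FALSE)
    maps[[length(maps) + 1L]] <- new("ItemMap", identifier = keyVals[[1L]],
                                     conceptKey = resource@conceptKey,
                                     properties = props)
  }
  attr(maps, "skips") <- skips
  maps
}

itemPropertyStatements <- function(itemURI, props, model) {
  if (!nrow(props)) return(emptyStatements())
  prefixes <- modelPrefixes(model)
  predURIs <- expandCURIE(props$predicate, prefixes)
  isObj <- props$kind == "uri" | predURIs %in% objectProperties()
  makeStatements(subject = itemURI, predicate = predURIs,
                 object = props$value,
                 objectKind = ifelse(isObj, "uri", "literal"))
}

#' Triplify one item map into the knowledge base
#'
#' Adds the structural statements (rdf:type Item, hasConcept plus its
#' materialized inverse, and an rdfs:label from the labeling rule) and one
#' statement per (predicate, value) pair of the map. The label defaults to
#' "concept label + identifier" unless a selector maps rdfs:label
#' explicitly.
#'
#' @param item An \linkS4class{ItemMap}.
#' @param model The \linkS4class{SeedModel}.
#' @param kb The target \linkS4class{KnowledgeBase}.
#' @return Number of statements actually new (mirrors included), invisibly.
#' @export
triplify <- function(item, model, kb) {
  con <- model@concepts[[item@conceptKey]]
  if (is.null(con))
    skbStop("seedkb_build_error",
            sprintf("item '%s' references unknown concept '%s'",
                    item@identifier, item@conceptKey))
  ns <- model@config@baseNamespace
  itemURI <- mintItemUri(item@conceptKey, item@identifier, ns)
  prefixes <- modelPrefixes(model)
  predURIs <- expandCURIE(item@properties$predicate, prefixes)
  structural <- rbind(
    makeStatements(itemURI, rdfType(), seedTerm("Item"), "uri"),
    makeStatements(itemURI, seedTerm("hasConcept"),
                   conceptURI(model, item@conceptKey), "uri"))
  if (!rdfsLabel() %in% predURIs)
    structural <- rbind(structural,
      makeStatements(itemURI, rdfsLabel(),
                     paste(con@label, item@identifier)))
  n <- addStatements(kb, structural)
  n <- n + addStatements(kb, itemPropertyStatements(itemURI, item@properties, model))
  invisible(n)
}

emptyFragment <- function(resource) {
  data.frame(resource = resource@key, method = resource@method,
             records = 0L, items = 0L, statements = 0L, links = 0L,
             skips = 0L, failed = FALSE, error = "",
             stringsAsFactors = FALSE)
}

itemsOfConcept <- function(kb, model, conceptKey) {
  cu <- conceptURI(model, conceptKey)
  st <- matchTriples(kb, predicate = seedTerm("hasConcept"), object = cu,
                     objectKind = "uri")
  uris <- unique(st$subject)
  prefix <- paste0(model@config@baseNamespace, tolower(conceptKey), "_")
  ids <- vapply(uris, function(u) {
    idSt <- matchTriples(kb, subject = u, predicate = dcTerm("identifier"))
    if (nrow(idSt)) idSt$object[[1L]]
    else percentDecode(localName(u, prefix))
  }, "", USE.NAMES = FALSE)
  data.frame(uri = uris, id = ids, stringsAsFactors = FALSE)
}

#' Run a cache resource: create new items from scratch
#'
#' @param resource A \linkS4class{ResourceDef} with method "cache".
#' @param model The \linkS4class{SeedModel}.
#' @param kb Target \linkS4class{KnowledgeBase}.
#' @param registry Endpoint registry (sparql connectors).
#' @param cache Per-run fetch cache environment.
#' @return One-row data.frame build-report fragment.
#' @export
runCache <- function(resource, model, kb, registry = NULL, cache = NULL) {
  frag <- emptyFragment(resource)
  rs <- selectRecords(resource, registry = registry, cache = cache)
  frag$records <- recordCount(rs)
  frag$skips <- nrow(rs@skips)
  maps <- makeItemMaps(rs, resource)
  frag$skips <- frag$skips + attr(maps, "skips")
  ids <- vapply(maps, slot, "", "identifier")
  checkMintCollisions(resource@conceptKey, ids, model@config@baseNamespace)
  before <- nrow(itemsOfConcept(kb, model, resource@conceptKey))
  n <- 0L
  for (m in maps) n <- n + triplify(m, model, kb)
  frag$items <- nrow(itemsOfConcept(kb, model, resource@conceptKey)) - before
  frag$statements <- n
  frag
}

#' Run a complete resource: append properties to existing items
#'
#' For every existing item of the extended concept the endpoint is resolved
#' by substituting the item identifier for \code{#replace#} and the
#' selected values are appended to that same item URI. An endpoint without
#' the token is fetched once and records are joined to items by
#' key-selector value equality. Creates no new items; per-item fetch
#' failures skip that item and continue.
#'
#' @inheritParams runCache
#' @return One-row data.frame build-report fragment.
#' @export
runComplete <- function(resource, model, kb, registry = NULL, cache = NULL) {
  frag <- emptyFragment(resource)
  items <- itemsOfConcept(kb, model, resource@extendsKey)
  perItem <- grepl("#replace#", resource@endpoint, fixed = TRUE)
  n <- 0L
  if (perItem) {
    for (i in seq_len(nrow(items))) {
      rs <- tryCatch(selectRecords(resource, id = items$id[i],
                                   registry = registry, cache = cache),
                     seedkb_fetch_error = function(e) NULL)
      if (is.null(rs)) { frag$skips <- frag$skips + 1L; next }
      frag$records <- frag$records + recordCount(rs)
      for (rec in rs@records) {
        props <- recordProperties(rec, NULL, resource)
        n <- n + addStatements(kb, itemPropertyStatements(items$uri[i], props, model))
      }
    }
  } else {
    rs <- selectRecords(resource, registry = registry, cache = cache)
    frag$records <- recordCount(rs)
    frag$skips <- nrow(rs@skips)
    maps <- makeItemMaps(rs, resource)
    frag$skips <- frag$skips + attr(maps, "skips")
    byId <- stats::setNames(items$uri, items$id)
    for (m in maps) {
      if (!m@identifier %in% names(byId)) { frag$skips <- frag$skips + 1L; next }
      uri <- byId[[m@identifier]]
      n <- n + addStatements(kb, itemPropertyStatements(uri, m@properties, model))
    }
  }
  frag$statements <- n
  frag
}

## Cross-product of a raw record's selector values and properties.
recordProperties <- function(rec, knd, resource) {
  rows <- list()
  for (sel in resource@selectors) {
    vals <- rec[[sel@key]] %||% character()
    if (!length(vals)) next
    kinds <- knd[[sel@key]] %||% rep("literal", length(vals))
    if (length(kinds) != length(vals)) kinds <- rep("literal", length(vals))
    for (p in sel@properties)
      rows[[length(rows) + 1L]] <- data.frame(predicate = p, value = vals,
                                              kind = kinds,
                                              stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(predicate = character(), value = character(),
                  kind = character(), stringsAsFactors = FALSE)
}

#' Run a map resource: link existing items with object properties
#'
#' The key selector carries the source identifier (items of the resource's
#' concept); the selector whose properties include the reserved marker
#' \code{seed:isAssociatedTo} carries the target identifier (items of the
#' extended concept). Each valid pair gains an isAssociatedTo link in both
#' directions; records referencing a missing item are logged skips. Adds no
#' literal properties and no new items.
#'
#' @inheritParams runCache
#' @return One-row data.frame build-report fragment.
#' @export
runMap <- function(resource, model, kb, registry = NULL, cache = NULL) {
  frag <- emptyFragment(resource)
  rs <- selectRecords(resource, registry = registry, cache = cache)
  frag$records <- recordCount(rs)
  frag$skips <- nrow(rs@skips)
  keyIdx <- which(vapply(resource@selectors, slot, TRUE, "isKey"))
  marker <- seedTerm("isAssociatedTo")
  tgtIdx <- which(vapply(resource@selectors, function(s)
    !s@isKey && any(expandCURIE(s@properties, modelPrefixes(model)) == marker),
    TRUE))
  if (length(keyIdx) != 1L || length(tgtIdx) < 1L)
    skbStop("seedkb_config_error",
            sprintf("map resource '%s' needs a key selector and a target selector marked seed:isAssociatedTo",
                    resource@key))
  keyHandle <- resource@selectors[[keyIdx]]@key
  tgtHandle <- resource@selectors[[tgtIdx[[1L]]]]@key
  ns <- model@config@baseNamespace
  n <- 0L
  for (rec in rs@records) {
    src <- rec[[keyHandle]]; tgt <- rec[[tgtHandle]]
    if (!length(src) || !length(tgt)) { frag$skips <- frag$skips + 1L; next }
    srcURI <- mintItemUri(resource@conceptKey, src[[1L]], ns)
    tgtURI <- mintItemUri(resource@extendsKey, tgt[[1L]], ns)
    if (!hasSubject(kb, srcURI) || !hasSubject(kb, tgtURI)) {
      frag$skips <- frag$skips + 1L; next
    }
    n <- n + addStatements(kb, makeStatements(srcURI, marker, tgtURI, "uri"))
    frag$links <- frag$links + 1L
  }
  frag$statements <- n
  frag
}

seedStructureStatements <- function(model) {
  ns <- model@config@baseNamespace
  seedURI <- paste0(ns, "seed_",
                    percentEncode(tolower(gsub("\\s+", "_", model@config@name))))
  out <- list(
    makeStatements(seedURI, rdfType(), seedTerm("Seed"), "uri"),
    makeStatements(seedURI, rdfsLabel(), model@config@name))
  for (ent in model@entities) {
    u <- paste0(ns, "entity_", ent@key)
    out <- c(out, list(
      makeStatements(seedURI, seedTerm("includes"), u, "uri"),
      makeStatements(u, rdfType(), seedTerm("Entity"), "uri"),
      makeStatements(u, rdfsLabel(), ent@label)))
    for (ck in ent@conceptKeys)
      out <- c(out, list(makeStatements(u, seedTerm("isEntityOf"),
                                        conceptURI(model, ck), "uri")))
  }
  for (con in model@concepts) {
    u <- conceptURI(model, con@key)
    out <- c(out, list(
      makeStatements(u, rdfType(), seedTerm("Concept"), "uri"),
      makeStatements(u, rdfsLabel(), con@label)))
    for (rk in con@resourceRefs) {
      ru <- paste0(ns, "resource_", rk)
      out <- c(out, list(
        makeStatements(u, seedTerm("hasResource"), ru, "uri"),
        makeStatements(ru, rdfType(), seedTerm("Resource"), "uri")))
    }
  }
  do.call(rbind, out)
}

#' Build a seed knowledge base
#'
#' Writes the Seed/Entity/Concept structure into the store, then executes
#' every resource in dependency order. A resource-level failure marks that
#' resource failed in the report and the build continues with the rest.
#'
#' @param model A valid \linkS4class{SeedModel}.
#' @param kb Target \linkS4class{KnowledgeBase} (created when NULL).
#' @param registry Endpoint registry for sparql connectors and SERVICE.
#' @return A \linkS4class{BuildReport}; the knowledge base is available as
#'   its attribute \code{"kb"}.
#' @export
buildSeed <- function(model, kb = NULL, registry = NULL) {
  issues <- validateModel(model)
  if (nrow(issues))
    skbStop("seedkb_validation_error",
            paste0("model has ", nrow(issues), " validation issue(s); first: ",
                   issues$message[[1L]]), issues = issues)
  if (is.null(kb)) kb <- KnowledgeBase(modelPrefixes(model))
  registerPrefixes(kb, modelPrefixes(model))
  addStatements(kb, seedStructureStatements(model))
  ordering <- buildDependencyOrder(model)
  cache <- new.env(parent = emptyenv())
  frags <- list()
  for (key in ordering) {
    res <- model@resources[[key]]
    runner <- switch(res@method, cache = runCache, complete = runComplete,
                     map = runMap)
    frag <- tryCatch(runner(res, model, kb, registry, cache),
                     error = function(e) {
                       f <- emptyFragment(res)
                       f$failed <- TRUE
                       f$error <- conditionMessage(e)
                       f
                     })
    frags[[key]] <- frag
  }
  resources <- if (length(frags)) do.call(rbind, frags) else
    emptyFragment(new("ResourceDef", key = "none", kind = "csv"))[0, ]
  row.names(resources) <- NULL
  report <- new("BuildReport", resources = resources, ordering = ordering)
  attr(report, "kb") <- kb
  report
}

#' Did any resource fail during the build?
#' @param report A \linkS4class{BuildReport}.
#' @return Logical scalar (build exit status).
#' @export
buildFailed <- function(report) any(report@resources$failed)

#' Audit the Item structure of a knowledge base
#'
#' Checks, via the SPARQL engine, that every Item individual has exactly
#' one hasConcept link and that the concept holds the matching isConceptOf
#' statement.
#'
#' @param kb A \linkS4class{KnowledgeBase}.
#' @return data.frame(item, problem); empty when the store is consistent.
#' @export
auditItems <- function(kb) {
  res <- sparqlQuery(kb, paste0(
    "PREFIX seed: <", SEED_NS, ">\n",
    "SELECT ?item ?concept WHERE { ?item a seed:Item . ",
    "OPTIONAL { ?item seed:hasConcept ?concept } }"))
  sol <- res$solutions
  items <- unique(sol$item)
  out <- list()
  for (it in items) {
    cons <- sol$concept[sol$item == it]
    cons <- cons[!is.na(cons)]
    if (length(unique(cons)) != 1L) {
      out[[length(out) + 1L]] <- data.frame(
        item = decTerm(it)$value,
        problem = sprintf("%d hasConcept links", length(unique(cons))),
        stringsAsFactors = FALSE)
      next
    }
    itemURI <- decTerm(it)$value
    conURI <- decTerm(cons[[1L]])$value
    back <- matchTriples(kb, subject = conURI,
                         predicate = seedTerm("isConceptOf"), object = itemURI)
    if (!nrow(back))
      out[[length(out) + 1L]] <- data.frame(
        item = itemURI, problem = "missing isConceptOf mirror",
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(item = character(), problem = character(),
                  stringsAsFactors = FALSE)
}
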