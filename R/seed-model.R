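## The configuration model: parse the instance-properties file (config.js)
## and the setup graph into a SeedModel, validate the tree invariants,
## serialize back to RDF, and order resources for building.

#' Parse the instance-properties file (config.js)
#'
#' @param text JSON text, or a path to the file. Recognized keys: name,
#'   version, description, environment, namespace (the instance base
#'   namespace), prefixes (object), ontologies (array).
#' @return A \linkS4class{SeedConfig}.
#' @export
parseSeedConfig <- function(text) {
  if (file.exists(text) && !grepl("^\\s*\\{", text)) text <- readTextFile(text)
  js <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  prefixes <- unlist(js$prefixes %||% list())
  if (is.null(prefixes)) prefixes <- character()
  ns <- js$namespace %||% js$baseNamespace %||% "http://localhost/seed/"
  new("SeedConfig",
      name = as.character(js$name %||% ""),
      version = as.character(js$version %||% "0"),
      description = as.character(js$description %||% ""),
      environment = as.character(js$environment %||% "dev"),
      baseNamespace = as.character(ns),
      prefixes = prefixes,
      ontologyImports = as.character(js$ontologies %||% character()))
}

#' Serialize a SeedConfig back to config.js JSON
#' @param config A \linkS4class{SeedConfig}.
#' @return JSON text.
#' @export
serializeSeedConfig <- function(config) {
  as.character(jsonlite::toJSON(list(
    name = config@name, version = config@version,
    description = config@description, environment = config@environment,
    namespace = config@baseNamespace,
    prefixes = as.list(config@prefixes),
    ontologies = config@ontologyImports), auto_unbox = TRUE, pretty = TRUE))
}

#' Full prefix map of a model
#' @param model A \linkS4class{SeedModel} (or \linkS4class{SeedConfig}).
#' @return Named character vector: built-ins, the instance namespace under
#'   the empty-string/"base" prefix, and user prefixes.
#' @export
modelPrefixes <- function(model) {
  config <- if (is(model, "SeedModel")) model@config else model
  p <- basePrefixes()
  p[names(config@prefixes)] <- config@prefixes
  p
}

stripTypePrefix <- function(local) {
  sub("^(entity|concept|resource|bridge)_", "", local)
}

uriLocal <- function(uri, namespaces) {
  for (ns in namespaces[order(nchar(namespaces), decreasing = TRUE)])
    if (startsWith(uri, ns)) return(substring(uri, nchar(ns) + 1L))
  sub("^.*[/#]", "", uri)
}

#' Parse a setup graph into a SeedModel
#'
#' Reads the RDF setup document (RDF/XML as shipped, Turtle also accepted),
#' collects every individual typed by a class of the internal vocabulary
#' and assembles the Entity-Concept-Resource-Bridge tree. Statements using
#' predicates outside the vocabulary are preserved verbatim: on resources
#' and bridges they land in the open property map, elsewhere in the model's
#' \code{extras} table. Unresolved cross-references are reported through
#' \code{\link{validateModel}} (and a warning), never silently dropped.
#'
#' @param text Setup document text, or a path to it.
#' @param config A \linkS4class{SeedConfig}.
#' @param format "auto" (default), "rdfxml" or "turtle".
#' @param quiet Suppress the validation warning.
#' @return A \linkS4class{SeedModel}.
#' @export
parseSetup <- function(text, config = new("SeedConfig", name = "seed"),
                       format = "auto", quiet = FALSE) {
  if (!grepl("[<@\n]", text) && file.exists(text)) text <- readTextFile(text)
  parsed <- parseRDF(text, format)
  st <- parsed$statements
  prefixes <- modelPrefixes(config)
  prefixes[names(parsed$prefixes)] <- parsed$prefixes
  ns <- config@baseNamespace
  nss <- unique(c(ns, unname(prefixes)))

  types <- st[st$predicate == rdfType(), , drop = FALSE]
  inVocab <- startsWith(types$object, SEED_NS)
  vocabName <- localName(types$object, SEED_NS)
  unknown <- inVocab & !vocabName %in% VOCAB_CLASSES
  if (any(unknown))
    skbStop("seedkb_validation_error",
            paste("individual typed by unknown vocabulary class:",
                  paste(unique(types$subject[unknown]), collapse = ", ")))
  typeOf <- stats::setNames(vocabName[inVocab], types$subject[inVocab])

  prop <- function(subj, pred, kind = NULL) {
    rows <- st[st$subject == subj & st$predicate == pred, , drop = FALSE]
    if (!is.null(kind)) rows <- rows[rows$objectKind == kind, , drop = FALSE]
    rows$object
  }
  lit1 <- function(subj, pred, default = NA_character_) {
    v <- prop(subj, pred)
    if (length(v)) v[[1L]] else default
  }
  keyOf <- function(uri) stripTypePrefix(uriLocal(uri, nss))

  subjOf <- function(class) names(typeOf)[typeOf == class]
  consumed <- rep(FALSE, nrow(st))
  markConsumed <- function(subj) consumed[st$subject %in% subj] <<- TRUE

  ## selectors first so resources can resolve them
  selectorSubjects <- names(typeOf)[typeOf %in% SELECTOR_CLASSES]
  selectors <- list()
  for (s in selectorSubjects) {
    props <- prop(s, seedTerm("property"))
    props <- unlist(strsplit(props, "[,[:space:]]+"))
    props <- props[nzchar(props)]
    selectors[[s]] <- new("Selector",
      key = uriLocal(s, nss),
      query = lit1(s, seedTerm("query"), ""),
      properties = props,
      isKey = identical(tolower(lit1(s, seedTerm("isKey"), "false")), "true"))
  }
  markConsumed(selectorSubjects)

  entities <- list()
  for (s in subjOf("Entity")) {
    key <- keyOf(s)
    conceptURIs <- unique(c(prop(s, seedTerm("isEntityOf"), "uri"),
                            st$subject[st$predicate == seedTerm("hasEntity") &
                                       st$object == s]))
    entities[[key]] <- new("EntityDef", key = key,
                           label = lit1(s, rdfsLabel(), key),
                           conceptKeys = vapply(conceptURIs, keyOf, "",
                                                USE.NAMES = FALSE))
  }
  markConsumed(subjOf("Entity"))

  concepts <- list()
  for (s in subjOf("Concept")) {
    key <- keyOf(s)
    entURIs <- unique(c(prop(s, seedTerm("hasEntity"), "uri"),
                        st$subject[st$predicate == seedTerm("isEntityOf") &
                                   st$object == s]))
    resURIs <- unique(c(prop(s, seedTerm("hasResource"), "uri"),
                        st$subject[st$predicate == seedTerm("isResourceOf") &
                                   st$object == s]))
    brURIs <- unique(c(prop(s, seedTerm("hasBridge"), "uri"),
                       st$subject[st$predicate == seedTerm("isBridgeOf") &
                                  st$object == s]))
    concepts[[key]] <- new("ConceptDef", key = key,
      entityKey = if (length(entURIs)) keyOf(entURIs[[1L]]) else NA_character_,
      label = lit1(s, rdfsLabel(), key),
      resourceRefs = vapply(resURIs, keyOf, "", USE.NAMES = FALSE),
      bridgeRefs = vapply(brURIs, keyOf, "", USE.NAMES = FALSE))
    if (length(entURIs) > 1L)
      concepts[[key]]@entityKey <- keyOf(entURIs[[1L]])  # extras flagged by validate
  }
  markConsumed(subjOf("Concept"))

  vocabPredURIs <- c(seedTerm(VOCAB_PREDICATES), rdfType(), rdfsLabel(),
                     dcTerm("publisher"))
  resources <- list()
  for (s in subjOf("Resource")) {
    key <- keyOf(s)
    selURIs <- prop(s, seedTerm("loadsFrom"))
    sels <- selectors[intersect(selURIs, names(selectors))]
    names(sels) <- NULL
    hint <- lit1(s, dcTerm("publisher"), "")
    kind <- tolower(hint)
    if (!kind %in% names(SELECTOR_CLASSES)) {
      kinds <- tolower(unique(typeOf[intersect(selURIs, names(typeOf))]))
      kind <- if (length(kinds)) kinds[[1L]] else "csv"
    }
    conceptURIs <- unique(c(prop(s, seedTerm("isResourceOf"), "uri"),
                            st$subject[st$predicate == seedTerm("hasResource") &
                                       st$object == s]))
    extendsURI <- prop(s, seedTerm("extends"))
    rowsExtra <- st[st$subject == s &
                    !st$predicate %in% vocabPredURIs, , drop = FALSE]
    extras <- split(rowsExtra$object, compactURI(rowsExtra$predicate, prefixes))
    sels <- defaultKeySelector(sels)
    resources[[key]] <- new("ResourceDef", key = key, kind = kind,
      method = lit1(s, seedTerm("method"), "cache"),
      endpoint = lit1(s, seedTerm("endpoint"), ""),
      connectorHint = if (nzchar(hint)) hint else kind,
      conceptKey = if (length(conceptURIs)) keyOf(conceptURIs[[1L]]) else NA_character_,
      extendsKey = if (length(extendsURI)) keyOf(extendsURI[[1L]]) else NA_character_,
      selectors = sels,
      order = as.integer(lit1(s, seedTerm("order"), "0")),
      extras = extras)
  }
  markConsumed(subjOf("Resource"))

  bridges <- list()
  for (s in subjOf("Bridge")) {
    key <- keyOf(s)
    conceptURIs <- unique(c(prop(s, seedTerm("isBridgeOf"), "uri"),
                            st$subject[st$predicate == seedTerm("hasBridge") &
                                       st$object == s]))
    rowsExtra <- st[st$subject == s &
                    !st$predicate %in% vocabPredURIs, , drop = FALSE]
    bridges[[key]] <- new("BridgeDef", key = key,
      conceptKey = if (length(conceptURIs)) keyOf(conceptURIs[[1L]]) else NA_character_,
      pattern = lit1(s, seedTerm("query"), lit1(s, seedTerm("endpoint"), "")),
      extraProperties = split(rowsExtra$object,
                              compactURI(rowsExtra$predicate, prefixes)))
  }
  markConsumed(subjOf("Bridge"))
  markConsumed(subjOf("Seed"))

  extras <- st[!consumed & !st$subject %in% names(typeOf), , drop = FALSE]
  row.names(extras) <- NULL
  model <- new("SeedModel", config = config, entities = entities,
               concepts = concepts, resources = resources, bridges = bridges,
               extras = extras)
  issues <- validateModel(model)
  if (nrow(issues) && !quiet)
    skbWarn("seedkb_validation_warning",
            paste0("setup graph has ", nrow(issues), " validation issue(s): ",
                   paste(utils::head(issues$message, 3L), collapse = "; ")))
  model
}

## Key-selector designation: explicit isKey wins; otherwise the selector
## whose properties include dc:identifier becomes the key selector.
defaultKeySelector <- function(sels) {
  if (!length(sels)) return(sels)
  flags <- vapply(sels, slot, TRUE, "isKey")
  if (any(flags)) return(sels)
  hasId <- vapply(sels, function(s)
    any(expandCURIE(s@properties, basePrefixes()) == dcTerm("identifier")), TRUE)
  if (any(hasId)) sels[[which(hasId)[1L]]]@isKey <- TRUE
  sels
}

#' Validate the tree invariants of a SeedModel
#'
#' Violations are data, not exceptions: each row names the offending
#' subject, the rule broken and a human-readable message. An empty result
#' means the model satisfies every invariant.
#'
#' @param model A \linkS4class{SeedModel}.
#' @return data.frame(subject, rule, message).
#' @export
validateModel <- function(model) {
  v <- list()
  bad <- function(subject, rule, message)
    v[[length(v) + 1L]] <<- data.frame(subject = subject, rule = rule,
                                       message = message,
                                       stringsAsFactors = FALSE)
  pfx <- model@config@prefixes
  badPfx <- pfx[!isAbsoluteURI(pfx)]
  for (p in names(badPfx))
    bad(p, "prefix-uri", sprintf("prefix '%s' is not an absolute URI", p))
  for (ent in model@entities) {
    missing <- setdiff(ent@conceptKeys, names(model@concepts))
    for (m in missing)
      bad(ent@key, "entity-concept-ref",
          sprintf("entity '%s' lists unknown concept '%s'", ent@key, m))
  }
  for (con in model@concepts) {
    if (is.na(con@entityKey))
      bad(con@key, "concept-entity",
          sprintf("concept '%s' lacks a hasEntity link", con@key))
    else if (!con@entityKey %in% names(model@entities))
      bad(con@key, "concept-entity-ref",
          sprintf("concept '%s' references unknown entity '%s'",
                  con@key, con@entityKey))
    else {
      ent <- model@entities[[con@entityKey]]
      if (!con@key %in% ent@conceptKeys)
        bad(con@key, "concept-entity-bidirectional",
            sprintf("entity '%s' does not list concept '%s' back",
                    con@entityKey, con@key))
    }
    for (m in setdiff(con@resourceRefs, names(model@resources)))
      bad(con@key, "concept-resource-ref",
          sprintf("concept '%s' lists unknown resource '%s'", con@key, m))
  }
  for (res in model@resources) {
    if (!res@method %in% c("cache", "complete", "map"))
      bad(res@key, "resource-method",
          sprintf("resource '%s' has unknown method '%s'", res@key, res@method))
    needsExtends <- res@method %in% c("complete", "map")
    if (needsExtends && is.na(res@extendsKey))
      bad(res@key, "resource-extends",
          sprintf("resource '%s' uses method '%s' but has no extends link",
                  res@key, res@method))
    if (!needsExtends && !is.na(res@extendsKey))
      bad(res@key, "resource-extends",
          sprintf("resource '%s' uses method 'cache' but declares extends",
                  res@key))
    if (!is.na(res@extendsKey) && !res@extendsKey %in% names(model@concepts))
      bad(res@key, "resource-extends-ref",
          sprintf("resource '%s' extends unknown concept '%s'",
                  res@key, res@extendsKey))
    if (is.na(res@conceptKey) || !res@conceptKey %in% names(model@concepts))
      bad(res@key, "resource-concept-ref",
          sprintf("resource '%s' is not attached to a known concept", res@key))
    nKey <- sum(vapply(res@selectors, slot, TRUE, "isKey"))
    if (length(res@selectors) && nKey != 1L)
      bad(res@key, "selector-key-cardinality",
          sprintf("resource '%s' has %d key selectors (exactly 1 expected)",
                  res@key, nKey))
    if (res@kind == "csv") {
      for (sel in res@selectors) {
        q <- suppressWarnings(as.integer(sel@query))
        if (is.na(q) || q < 0L)
          bad(sel@key, "csv-selector-query",
              sprintf("CSV selector '%s' query '%s' is not a column index >= 0",
                      sel@key, sel@query))
      }
    }
  }
  for (br in model@bridges) {
    if (is.na(br@conceptKey) || !br@conceptKey %in% names(model@concepts))
      bad(br@key, "bridge-concept-ref",
          sprintf("bridge '%s' is not attached to a known concept", br@key))
  }
  ## warn-level: mixed-method resources on one concept sharing an endpoint
  eps <- lapply(model@resources, function(r) c(r@conceptKey, r@endpoint, r@method))
  if (length(eps) > 1L) {
    df <- as.data.frame(do.call(rbind, eps), stringsAsFactors = FALSE)
    names(df) <- c("concept", "endpoint", "method")
    dup <- df[nzchar(df$endpoint), , drop = FALSE]
    key <- paste(dup$concept, dup$endpoint)
    for (k in unique(key[duplicated(key)])) {
      methods <- unique(dup$method[key == k])
      if (length(methods) > 1L)
        skbWarn("seedkb_config_warning",
                sprintf("concept/endpoint pair '%s' has resources with mixed methods (%s)",
                        k, paste(methods, collapse = ", ")))
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(subject = character(), rule = character(),
                  message = character(), stringsAsFactors = FALSE)
}

modelStatements <- function(model) {
  ns <- model@config@baseNamespace
  prefixes <- modelPrefixes(model)
  out <- list()
  add <- function(...) out[[length(out) + 1L]] <<- makeStatements(...)
  entURI <- function(k) paste0(ns, "entity_", k)
  conURI <- function(k) paste0(ns, "concept_", k)
  resURI <- function(k) paste0(ns, "resource_", k)
  brURI  <- function(k) paste0(ns, "bridge_", k)
  for (ent in model@entities) {
    u <- entURI(ent@key)
    add(u, rdfType(), seedTerm("Entity"), "uri")
    add(u, rdfsLabel(), ent@label)
    for (ck in ent@conceptKeys) add(u, seedTerm("isEntityOf"), conURI(ck), "uri")
  }
  for (con in model@concepts) {
    u <- conURI(con@key)
    add(u, rdfType(), seedTerm("Concept"), "uri")
    add(u, rdfsLabel(), con@label)
    if (!is.na(con@entityKey)) add(u, seedTerm("hasEntity"), entURI(con@entityKey), "uri")
    for (rk in con@resourceRefs) add(u, seedTerm("hasResource"), resURI(rk), "uri")
    for (bk in con@bridgeRefs) add(u, seedTerm("hasBridge"), brURI(bk), "uri")
  }
  for (res in model@resources) {
    u <- resURI(res@key)
    add(u, rdfType(), seedTerm("Resource"), "uri")
    add(u, dcTerm("publisher"), res@connectorHint)
    add(u, seedTerm("method"), res@method)
    if (nzchar(res@endpoint)) add(u, seedTerm("endpoint"), res@endpoint)
    add(u, seedTerm("order"), as.character(res@order))
    if (!is.na(res@conceptKey))
      add(u, seedTerm("isResourceOf"), conURI(res@conceptKey), "uri")
    if (!is.na(res@extendsKey))
      add(u, seedTerm("extends"), conURI(res@extendsKey), "uri")
    for (sel in res@selectors) {
      su <- paste0(ns, sel@key)
      add(u, seedTerm("loadsFrom"), su, "uri")
      add(su, rdfType(), seedTerm(SELECTOR_CLASSES[[res@kind]]), "uri")
      add(su, seedTerm("query"), sel@query)
      for (p in sel@properties) add(su, seedTerm("property"), p)
      if (sel@isKey) add(su, seedTerm("isKey"), "true")
    }
    for (p in names(res@extras))
      add(u, expandCURIE(p, prefixes), res@extras[[p]])
  }
  for (br in model@bridges) {
    u <- brURI(br@key)
    add(u, rdfType(), seedTerm("Bridge"), "uri")
    if (!is.na(br@conceptKey))
      add(u, seedTerm("isBridgeOf"), conURI(br@conceptKey), "uri")
    if (nzchar(br@pattern)) add(u, seedTerm("query"), br@pattern)
    for (p in names(br@extraProperties))
      add(u, expandCURIE(p, prefixes), br@extraProperties[[p]])
  }
  st <- if (length(out)) do.call(rbind, out) else emptyStatements()
  dedupStatements(rbind(st, model@extras))
}

#' Serialize a SeedModel to a setup document
#'
#' \code{parseSetup(serializeModel(m), m@config)} reproduces \code{m}
#' key-by-key.
#'
#' @param model A \linkS4class{SeedModel}.
#' @param format "turtle" (default) or "rdfxml".
#' @return Document text.
#' @export
serializeModel <- function(model, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  serializeRDF(modelStatements(model), format, modelPrefixes(model))
}

#' Resource build order
#'
#' Topological sort of the resource dependency graph: a resource that
#' extends a concept runs after every resource attached to that concept.
#' Ties are broken by (order, key) ascending, so the result is
#' deterministic.
#'
#' @param model A \linkS4class{SeedModel}.
#' @return Character vector of resource keys in execution order.
#' @export
buildDependencyOrder <- function(model) {
  res <- model@resources
  keys <- names(res)
  if (!length(keys)) return(character())
  deps <- stats::setNames(vector("list", length(keys)), keys)
  for (k in keys) {
    ext <- res[[k]]@extendsKey
    if (is.na(ext)) next
    providers <- keys[vapply(res, function(r) identical(r@conceptKey, ext), TRUE)]
    deps[[k]] <- setdiff(providers, k)
  }
  ordKey <- function(k) sprintf("%012d\r%s", res[[k]]@order, k)
  done <- character()
  remaining <- keys
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(k)
      all(deps[[k]] %in% done), TRUE)]
    if (!length(ready))
      skbStop("seedkb_cycle_error",
              paste("dependency cycle among resources:",
                    paste(sort(remaining), collapse = ", ")),
              cycle = remaining)
    nxt <- ready[order(vapply(ready, ordKey, ""))][1L]
    done <- c(done, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  done
}

#' Structural equality of two seed models
#'
#' Key-by-key comparison of entities, concepts, resources (including
#' selectors) and bridges; used to verify the parse/serialize round-trip.
#'
#' @param a,b \linkS4class{SeedModel} objects.
#' @return Logical scalar.
#' @export
sameModel <- function(a, b) {
  cmpSet <- function(x, y) setequal(names(x), names(y))
  if (!cmpSet(a@entities, b@entities) || !cmpSet(a@concepts, b@concepts) ||
      !cmpSet(a@resources, b@resources) || !cmpSet(a@bridges, b@bridges))
    return(FALSE)
  for (k in names(a@entities)) {
    x <- a@entities[[k]]; y <- b@entities[[k]]
    if (x@label != y@label || !setequal(x@conceptKeys, y@conceptKeys))
      return(FALSE)
  }
  for (k in names(a@concepts)) {
    x <- a@concepts[[k]]; y <- b@concepts[[k]]
    if (!identical(x@entityKey, y@entityKey) || x@label != y@label ||
        !setequal(x@resourceRefs, y@resourceRefs) ||
        !setequal(x@bridgeRefs, y@bridgeRefs))
      return(FALSE)
  }
  for (k in names(a@resources)) {
    x <- a@resources[[k]]; y <- b@resources[[k]]
    if (x@kind != y@kind || x@method != y@method || x@endpoint != y@endpoint ||
        !identical(x@conceptKey, y@conceptKey) ||
        !identical(x@extendsKey, y@extendsKey) || x@order != y@order)
      return(FALSE)
    sx <- x@selectors[order(vapply(x@selectors, slot, "", "key"))]
    sy <- y@selectors[order(vapply(y@selectors, slot, "", "key"))]
    if (length(sx) != length(sy)) return(FALSE)
    for (i in seq_along(sx)) {
      if (sx[[i]]@key != sy[[i]]@key || sx[[i]]@query != sy[[i]]@query ||
          !setequal(sx[[i]]@properties, sy[[i]]@properties) ||
          sx[[i]]@isKey != sy[[i]]@isKey)
        return(FALSE)
    }
  }
  for (k in names(a@bridges)) {
    x <- a@bridges[[k]]; y <- b@bridges[[k]]
    if (!identical(x@conceptKey, y@conceptKey) || x@pattern != y@pattern)
      return(FALSE)
  }
  TRUE
}
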