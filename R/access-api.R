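## The exploration surface over a built knowledge base: triple-pattern
## queries with multi-format serialization, the SPARQL endpoint, LinkedData
## views, bridge URL resolution and SERVICE federation.

WILDCARDS <- list(subject = c("sub", "s"), predicate = c("pred", "p"),
                  object = c("obj", "o"))
ALL_WILDCARDS <- unlist(WILDCARDS, use.names = FALSE)

parsePatternToken <- function(token, position, prefixes) {
  if (token %in% WILDCARDS[[position]])
    return(list(value = NA_character_, kind = "wildcard"))
  if (token %in% ALL_WILDCARDS)
    skbStop("seedkb_client_error",
            sprintf("wildcard token '%s' is not valid in %s position",
                    token, position))
  if (startsWith(token, "\"") && endsWith(token, "\"") && nchar(token) >= 2L) {
    if (position != "object")
      skbStop("seedkb_client_error",
              sprintf("literal not allowed in %s position", position))
    return(list(value = substr(token, 2L, nchar(token) - 1L), kind = "literal"))
  }
  if (grepl(":", token, fixed = TRUE))
    return(list(value = expandCURIE(token, prefixes), kind = "uri"))
  if (position == "object")
    return(list(value = token, kind = "literal"))
  skbStop("seedkb_client_error",
          sprintf("'%s' in %s position is neither a wildcard, a CURIE nor a URI",
                  token, position))
}

#' Parse a triple pattern from its three tokens
#'
#' Wildcards are positional: sub/s, pred/p, obj/o — a wildcard token in the
#' wrong position is a client error. Everything else is a CURIE (resolved
#' through the prefix map), an absolute URI, or — in object position — a
#' literal.
#'
#' @param sub,pred,obj Pattern tokens.
#' @param prefixes Prefix map for CURIE resolution.
#' @return A list of parsed positions (class "TriplePattern").
#' @export
parseTriplePattern <- function(sub, pred, obj, prefixes = basePrefixes()) {
  structure(list(subject = parsePatternToken(sub, "subject", prefixes),
                 predicate = parsePatternToken(pred, "predicate", prefixes),
                 object = parsePatternToken(obj, "object", prefixes)),
            class = "TriplePattern")
}

OUTPUT_TOKENS <- c("csv", "js", "xml", "rdf", "html")

checkFormat <- function(format) {
  if (!isString(format) || !format %in% OUTPUT_TOKENS)
    skbStop("seedkb_client_error",
            sprintf("unknown output format '%s' (expected one of %s)",
                    format, paste(OUTPUT_TOKENS, collapse = ", ")))
  format
}

matchPatternStatements <- function(pattern, kb) {
  obj <- pattern$object
  matchTriples(kb,
    subject = pattern$subject$value,
    predicate = pattern$predicate$value,
    object = obj$value,
    objectKind = if (obj$kind %in% c("uri", "literal")) obj$kind else NULL)
}

htmlTable <- function(statements, title) {
  rows <- vapply(seq_len(nrow(statements)), function(i) {
    sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
            xmlEscape(statements$subject[i]), xmlEscape(statements$predicate[i]),
            xmlEscape(statements$object[i]))
  }, "")
  paste0("<!DOCTYPE html>\n<html><head><title>", xmlEscape(title),
         "</title></head><body><h1>", xmlEscape(title), "</h1>",
         "<table><tr><th>subject</th><th>predicate</th><th>object</th></tr>",
         paste(rows, collapse = ""), "</table></body></html>\n")
}

#' Serialize a statement set in an output format
#'
#' csv: a table with subject/predicate/object plus term-kind columns;
#' js: SPARQL-results JSON over variables subject/predicate/object;
#' xml and rdf: RDF/XML; html: a readable summary table. csv, js and xml
#' outputs all deserialize back to the same statement set (see
#' \code{\link{parseTripleResult}}).
#'
#' @param statements Statement data.frame.
#' @param format One of csv, js, xml, rdf, html.
#' @param prefixes Prefix map for RDF serialization.
#' @param title Heading used by the html format.
#' @return A single string.
#' @export
serializeTriples <- function(statements, format, prefixes = basePrefixes(),
                             title = "Statements") {
  checkFormat(format)
  if (format %in% c("xml", "rdf"))
    return(serializeRDFXML(statements, prefixes))
  if (format == "html")
    return(htmlTable(statements, title))
  sol <- if (nrow(statements)) data.frame(
    subject = paste0("<", statements$subject, ">"),
    predicate = paste0("<", statements$predicate, ">"),
    object = encodeObjects(statements),
    stringsAsFactors = FALSE)
  else data.frame(subject = character(), predicate = character(),
                  object = character(), stringsAsFactors = FALSE)
  res <- list(type = "select", vars = c("subject", "predicate", "object"),
              solutions = sol)
  serializeSparqlResult(res, output = format, prefixes = prefixes)
}

#' Deserialize a triple-API result back into statements
#'
#' Inverse of \code{\link{serializeTriples}} for the machine formats.
#'
#' @param text Serialized document.
#' @param format One of csv, js, xml, rdf.
#' @return Statement data.frame.
#' @export
parseTripleResult <- function(text, format) {
  checkFormat(format)
  if (format %in% c("xml", "rdf")) return(parseRDFXML(text)$statements)
  if (format == "js") {
    js <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    rows <- lapply(js$results$bindings, function(b) {
      toEnc <- function(f) {
        if (f$type == "uri") return(list(v = f$value, k = "uri", l = "", d = ""))
        list(v = f$value, k = "literal", l = f[["xml:lang"]] %||% "",
             d = f$datatype %||% "")
      }
      o <- toEnc(b$object)
      makeStatements(b$subject$value, b$predicate$value, o$v, o$k, o$l, o$d)
    })
    return(dedupStatements(if (length(rows)) do.call(rbind, rows)
                           else emptyStatements()))
  }
  df <- utils::read.csv(text = text, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!nrow(df)) return(emptyStatements())
  makeStatements(df$subject, df$predicate, df$object,
                 objectKind = df$object_kind,
                 lang = df$object_lang, datatype = df$object_datatype)
}

#' Query the knowledge base with a triple pattern
#'
#' Returns all statements matching the pattern (wildcards unbound),
#' serialized in the requested format; an empty match yields an
#' empty-but-valid document.
#'
#' @param sub,pred,obj Pattern tokens (wildcards: sub/s, pred/p, obj/o),
#'   or a parsed pattern passed as \code{sub}.
#' @param format Output token: csv, js, xml, rdf or html.
#' @param kb A \linkS4class{KnowledgeBase}.
#' @return Serialized result string.
#' @examples
#' kb <- KnowledgeBase()
#' addStatements(kb, makeStatements("http://x/i", "http://x/p", "v"))
#' getTriple("<http://x/i>", "p", "o", "csv", kb)
#' @export
getTriple <- function(sub, pred, obj, format, kb) {
  checkFormat(format)
  pattern <- if (inherits(sub, "TriplePattern")) sub
             else parseTriplePattern(sub, pred, obj, kbPrefixes(kb))
  st <- matchPatternStatements(pattern, kb)
  serializeTriples(st, format, kbPrefixes(kb), title = "Triple pattern result")
}

#' Parse a REST triple route
#'
#' The route grammar is \code{.../api/triple/<sub>/<pred>/<obj>/<format>}:
#' exactly four segments after the route prefix.
#'
#' @param path URL path.
#' @param prefixes Prefix map for CURIE resolution.
#' @return list(pattern, format).
#' @export
parseTripleRoute <- function(path, prefixes = basePrefixes()) {
  rest <- sub("^.*?/api/triple/", "", path)
  if (identical(rest, path)) rest <- sub("^/+", "", path)
  segments <- strsplit(rest, "/", fixed = TRUE)[[1L]]
  segments <- segments[nzchar(segments)]
  if (length(segments) != 4L)
    skbStop("seedkb_route_error",
            sprintf("triple route needs 4 segments, got %d", length(segments)),
            status = 404L)
  format <- checkFormat(utils::URLdecode(segments[[4L]]))
  tokens <- vapply(segments[1:3], utils::URLdecode, "")
  list(pattern = parseTriplePattern(tokens[[1L]], tokens[[2L]], tokens[[3L]],
                                    prefixes),
       format = format)
}

#' SPARQL endpoint with format negotiation
#'
#' Executes a read-only SPARQL query. SELECT/ASK results honour the
#' \code{output} parameter (csv, js, xml); CONSTRUCT/DESCRIBE return RDF.
#' Update forms and parse errors are client errors. When \code{output} is
#' absent, SPARQL-results XML is used.
#'
#' @param query SPARQL query text.
#' @param output Output token; default "xml".
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param registry Optional endpoint registry for SERVICE clauses.
#' @return Serialized result string.
#' @export
sparqlEndpoint <- function(query, output = "xml", kb, registry = NULL) {
  if (!output %in% c("csv", "js", "xml", "rdf"))
    skbStop("seedkb_client_error",
            sprintf("unknown output format '%s'", output))
  res <- sparqlQuery(kb, query, registry)
  serializeSparqlResult(res, output, kbPrefixes(kb))
}

#' LinkedData view of one resource
#'
#' Dereferences a local name under the instance namespace: rdf mode lists
#' every statement in which the resource is the subject; html mode renders
#' the same statements as a summary page headed by the resource's
#' rdfs:label. An unknown resource yields an empty description with a
#' not-found status.
#'
#' @param localName Resource local name, e.g. "uniprot_P51587".
#' @param mode "rdf" or "html".
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param namespace Instance namespace the local name resolves under.
#' @return list(document, status, statements).
#' @export
linkedDataView <- function(localName, mode = c("rdf", "html"), kb,
                           namespace) {
  mode <- match.arg(mode)
  uri <- paste0(namespace, localName)
  st <- matchTriples(kb, subject = uri)
  status <- if (nrow(st)) 200L else 404L
  doc <- if (mode == "rdf") {
    serializeRDFXML(st, kbPrefixes(kb))
  } else {
    labels <- st$object[st$predicate == rdfsLabel()]
    title <- if (length(labels)) labels[[1L]] else localName
    htmlTable(st, title)
  }
  list(document = doc, status = status, statements = st)
}

#' Resolve a bridge URL for an item
#'
#' Substitutes every \code{#replace#} token in the bridge pattern with the
#' item identifier.
#'
#' @param bridge A \linkS4class{BridgeDef} (or a pattern string).
#' @param itemId Item identifier.
#' @return URL string.
#' @examples
#' resolveBridge("http://www.uniprot.org/uniprot/#replace#", "P51587")
#' @export
resolveBridge <- function(bridge, itemId) {
  if (!isString(itemId) || !nzchar(itemId))
    skbStop("seedkb_client_error", "item identifier must be nonempty")
  pattern <- if (is(bridge, "BridgeDef")) bridge@pattern else bridge
  resolveTemplate(pattern, itemId)
}

#' Execute a federated SPARQL query
#'
#' SERVICE clauses are resolved through the endpoint registry and joined in
#' clause order by binding propagation. An unreachable SERVICE endpoint
#' raises an error naming it — never silent partial results. A query with
#' no SERVICE clause behaves exactly like \code{\link{sparqlEndpoint}} on
#' \code{kb}.
#'
#' @param query SPARQL query text with zero or more SERVICE clauses.
#' @param registry Endpoint registry mapping URIs to knowledge bases.
#' @param kb Local \linkS4class{KnowledgeBase} for non-SERVICE patterns;
#'   defaults to an empty store.
#' @return Result object from \code{\link{sparqlQuery}}.
#' @export
federatedQuery <- function(query, registry, kb = NULL) {
  if (is.null(kb)) kb <- KnowledgeBase()
  sparqlQuery(kb, query, registry)
}
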