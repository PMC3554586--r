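## The seed triple store: set-semantics statement table with named graphs,
## write-time inverse materialization and pattern matching.

#' Create an empty knowledge base
#'
#' @param prefixes Named character vector of prefix -> namespace mappings
#'   layered over \code{\link{basePrefixes}}.
#' @return A \linkS4class{KnowledgeBase}.
#' @examples
#' kb <- KnowledgeBase()
#' addStatements(kb, makeStatements("http://x/s", "http://x/p", "v"))
#' kbSize(kb)
#' @export
KnowledgeBase <- function(prefixes = character()) {
  ptr <- new.env(parent = emptyenv())
  ptr$statements <- emptyStatements()
  ptr$keys <- character()
  base <- basePrefixes()
  extra <- prefixes[!names(prefixes) %in% names(base)]
  ptr$prefixes <- c(base, extra)
  new("KnowledgeBase", ptr = ptr)
}

#' @describeIn KnowledgeBase Number of statements in the store (all graphs).
#' @param kb A \linkS4class{KnowledgeBase}.
#' @export
kbSize <- function(kb) nrow(kb@ptr$statements)

#' Statements held in a knowledge base
#'
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param graph Optional graph name; default returns all graphs.
#' @return data.frame with columns subject, predicate, object, objectKind,
#'   lang, datatype, graph.
#' @export
kbStatements <- function(kb, graph = NULL) {
  st <- kb@ptr$statements
  if (!is.null(graph)) st <- st[st$graph == graph, , drop = FALSE]
  row.names(st) <- NULL
  st
}

#' Prefix map of a knowledge base
#' @param kb A \linkS4class{KnowledgeBase}.
#' @return Named character vector.
#' @export
kbPrefixes <- function(kb) kb@ptr$prefixes

#' Register prefixes on a knowledge base
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param prefixes Named character vector prefix -> namespace URI.
#' @return The knowledge base, invisibly.
#' @export
registerPrefixes <- function(kb, prefixes) {
  stopifnot(is.character(prefixes), !is.null(names(prefixes)))
  p <- kb@ptr$prefixes
  p[names(prefixes)] <- prefixes
  kb@ptr$prefixes <- p
  invisible(kb)
}

## Mirror statements for predicates with a registered inverse. Only
## URI-object statements can be mirrored.
mirrorStatements <- function(st) {
  inv <- inverseOf(st$predicate)
  sel <- !is.na(inv) & st$objectKind == "uri"
  if (!any(sel)) return(emptyStatements())
  m <- st[sel, , drop = FALSE]
  makeStatements(subject = m$object, predicate = inv[sel], object = m$subject,
                 objectKind = "uri", graph = m$graph)
}

#' Add statements to a knowledge base
#'
#' Statements already present are ignored (RDF set semantics). Statements
#' whose predicate belongs to a registered inverse pair are materialized in
#' both directions, so the triple-pattern API sees structural links from
#' either side.
#'
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param statements data.frame as produced by \code{\link{makeStatements}}.
#' @param mirror Materialize registered inverses (default TRUE).
#' @return Invisibly, the number of statements actually new (mirrors
#'   included).
#' @export
addStatements <- function(kb, statements, mirror = TRUE) {
  if (!nrow(statements)) return(invisible(0L))
  bad <- !isAbsoluteURI(statements$subject) | !isAbsoluteURI(statements$predicate)
  if (any(bad))
    skbStop("seedkb_build_error",
            sprintf("statement with non-absolute subject/predicate URI: %s %s",
                    statements$subject[which(bad)[1L]],
                    statements$predicate[which(bad)[1L]]))
  if (mirror) statements <- rbind(statements, mirrorStatements(statements))
  statements <- dedupStatements(statements)
  keys <- statementKey(statements)
  fresh <- !(keys %in% kb@ptr$keys)
  if (any(fresh)) {
    kb@ptr$statements <- rbind(kb@ptr$statements,
                               statements[fresh, , drop = FALSE])
    kb@ptr$keys <- c(kb@ptr$keys, keys[fresh])
    row.names(kb@ptr$statements) <- NULL
  }
  invisible(sum(fresh))
}

#' Match a triple pattern against the store
#'
#' \code{NULL} (or \code{NA}) in a position is a wildcard. Subject and
#' predicate match URIs; the object matches either the lexical value of a
#' literal or a URI, optionally restricted by \code{objectKind}.
#'
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param subject,predicate,object Bound values or NULL wildcards.
#' @param objectKind Optional "uri" or "literal" restriction.
#' @param graph Optional graph restriction.
#' @return data.frame of matching statements.
#' @export
matchTriples <- function(kb, subject = NULL, predicate = NULL, object = NULL,
                         objectKind = NULL, graph = NULL) {
  st <- kb@ptr$statements
  keep <- rep(TRUE, nrow(st))
  if (!is.null(subject) && !is.na(subject))   keep <- keep & st$subject == subject
  if (!is.null(predicate) && !is.na(predicate)) keep <- keep & st$predicate == predicate
  if (!is.null(object) && !is.na(object))     keep <- keep & st$object == object
  if (!is.null(objectKind))                   keep <- keep & st$objectKind == objectKind
  if (!is.null(graph))                        keep <- keep & st$graph == graph
  out <- st[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Test whether a URI occurs as a subject in the store
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param uri Absolute URI.
#' @return Logical scalar.
#' @export
hasSubject <- function(kb, uri) uri %in% kb@ptr$statements$subject

#' Graph-level equality of two knowledge bases
#'
#' The stores contain no blank nodes, so graph isomorphism reduces to set
#' equality of the statement tables (graph names ignored when
#' \code{ignoreGraphs}).
#'
#' @param a,b \linkS4class{KnowledgeBase} objects.
#' @param ignoreGraphs Compare the union of graphs as one set.
#' @return Logical scalar.
#' @export
sameGraph <- function(a, b, ignoreGraphs = FALSE) {
  sa <- kbStatements(a); sb <- kbStatements(b)
  if (ignoreGraphs) { sa$graph <- ""; sb$graph <- "" }
  setequal(statementKey(dedupStatements(sa)), statementKey(dedupStatements(sb)))
}

setMethod("show", "KnowledgeBase", function(object) {
  st <- object@ptr$statements
  cat(sprintf("KnowledgeBase with %d statements", nrow(st)))
  g <- setdiff(unique(st$graph), "")
  if (length(g)) cat(sprintf(" in %d named graphs", length(g)))
  cat(sprintf("; %d prefixes\n", length(object@ptr$prefixes)))
})

setMethod("show", "SeedModel", function(object) {
  cat(sprintf("SeedModel '%s' (v%s): %d entities, %d concepts, %d resources, %d bridges\n",
              object@config@name, object@config@version,
              length(object@entities), length(object@concepts),
              length(object@resources), length(object@bridges)))
})

setMethod("show", "RecordSet", function(object) {
  cat(sprintf("RecordSet: %d records from <%s>, %d skipped\n",
              length(object@records), object@sourceUri, nrow(object@skips)))
})

setMethod("show", "BuildReport", function(object) {
  cat(sprintf("BuildReport: %d resources in order [%s]\n",
              nrow(object@resources), paste(object@ordering, collapse = ", ")))
  print(object@resources)
})
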