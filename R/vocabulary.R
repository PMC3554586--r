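## The internal seed ontology: the class and predicate vocabulary every
## setup graph is written against, plus CURIE machinery.

SEED_NS  <- "http://seedkb.org/ontology/"
RDF_NS   <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS  <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS   <- "http://www.w3.org/2002/07/owl#"
XSD_NS   <- "http://www.w3.org/2001/XMLSchema#"
DC_NS    <- "http://purl.org/dc/elements/1.1/"

#' Built-in prefix map
#'
#' Prefixes known to every knowledge base before any configuration is read.
#' User prefixes from \code{config.js} are layered on top of these.
#'
#' @return Named character vector mapping prefix to namespace URI.
#' @export
basePrefixes <- function() {
  c(seed = SEED_NS, rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS,
    xsd = XSD_NS, dc = DC_NS)
}

## Vocabulary classes: the typed individuals a setup graph may contain.
VOCAB_CLASSES <- c("Seed", "Entity", "Concept", "Item", "Resource",
                   "CSV", "XML", "SQL", "SPARQL", "Bridge")

SELECTOR_CLASSES <- c(csv = "CSV", xml = "XML", sql = "SQL", sparql = "SPARQL")

VOCAB_PREDICATES <- c("includes", "isIncludedIn", "isEntityOf", "hasEntity",
                      "isConceptOf", "hasConcept", "isAssociatedTo",
                      "hasResource", "isResourceOf", "hasBridge", "isBridgeOf",
                      "loadsFrom", "isLoadedBy", "extends", "method",
                      "endpoint", "query", "property", "order", "isKey")

#' Vocabulary term URI
#'
#' Expands a term of the internal ontology (class or predicate name) to its
#' absolute URI.
#'
#' @param name Term name, e.g. \code{"Concept"} or \code{"hasConcept"}.
#' @return Absolute URI string.
#' @export
seedTerm <- function(name) paste0(SEED_NS, name)

#' URIs of common imported terms
#'
#' @return Absolute URI strings for rdf:type, rdfs:label and Dublin Core
#'   elements respectively.
#' @export
rdfType   <- function() paste0(RDF_NS, "type")

#' @rdname rdfType
#' @export
rdfsLabel <- function() paste0(RDFS_NS, "label")

#' @rdname rdfType
#' @param name Dublin Core element name, e.g. "identifier".
#' @export
dcTerm    <- function(name) paste0(DC_NS, name)

#' Registered inverse predicate pairs
#'
#' Structural predicates are materialized in both directions at write time,
#' so a plain triple-pattern query sees either side of every link without a
#' reasoner. \code{isAssociatedTo} is its own inverse (symmetric).
#'
#' @return A two-column character matrix; each row is an inverse pair of
#'   absolute predicate URIs.
#' @export
inversePairs <- function() {
  m <- rbind(c("includes",     "isIncludedIn"),
             c("isEntityOf",   "hasEntity"),
             c("isConceptOf",  "hasConcept"),
             c("hasResource",  "isResourceOf"),
             c("hasBridge",    "isBridgeOf"),
             c("loadsFrom",    "isLoadedBy"),
             c("isAssociatedTo", "isAssociatedTo"))
  matrix(seedTerm(m), ncol = 2L,
         dimnames = list(NULL, c("predicate", "inverse")))
}

## Lookup: predicate URI -> inverse URI (both directions), NA when none.
inverseOf <- function(predicate) {
  pairs <- inversePairs()
  fwd <- stats::setNames(pairs[, 2L], pairs[, 1L])
  rev <- stats::setNames(pairs[, 1L], pairs[, 2L])
  out <- fwd[predicate]
  miss <- is.na(out)
  out[miss] <- rev[predicate[miss]]
  unname(out)
}

#' Expand a CURIE to an absolute URI
#'
#' Accepts absolute URIs (returned unchanged, angle brackets stripped) and
#' \code{prefix:local} CURIEs resolved through the prefix map.
#'
#' @param x Character vector of CURIEs or URIs.
#' @param prefixes Named character vector prefix -> namespace; defaults to
#'   the built-in map.
#' @param default Namespace used for a bare \code{:local} CURIE.
#' @return Character vector of absolute URIs.
#' @export
expandCURIE <- function(x, prefixes = basePrefixes(), default = SEED_NS) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (startsWith(s, "<") && endsWith(s, ">"))
      return(substr(s, 2L, nchar(s) - 1L))
    if (!grepl(":", s, fixed = TRUE)) return(s)
    pfx <- sub(":.*$", "", s)
    rest <- sub("^[^:]*:", "", s)
    if (pfx == "") return(paste0(default, rest))
    if (pfx %in% names(prefixes)) return(paste0(prefixes[[pfx]], rest))
    ## recognised URI schemes pass through untouched; any other
    ## colon-qualified token is an unresolved CURIE prefix
    if (tolower(pfx) %in% c("http", "https", "file", "urn", "ftp", "mailto",
                            "tag", "doi", "sqlite", "jdbc", "endpoint"))
      return(s)
    skbStop("seedkb_client_error",
            sprintf("unresolvable CURIE prefix '%s' in '%s'", pfx, s))
  }, "", USE.NAMES = FALSE)
}

#' Compact an absolute URI to a CURIE where a prefix matches
#'
#' @param x Character vector of absolute URIs.
#' @param prefixes Named character vector prefix -> namespace.
#' @return CURIEs where a namespace matches, otherwise the input.
#' @export
compactURI <- function(x, prefixes = basePrefixes()) {
  ord <- order(nchar(prefixes), decreasing = TRUE)
  pfx <- prefixes[ord]
  vapply(x, function(u) {
    if (is.na(u)) return(NA_character_)
    for (i in seq_along(pfx)) {
      ns <- pfx[[i]]
      if (startsWith(u, ns) && nchar(u) > nchar(ns)) {
        loc <- substring(u, nchar(ns) + 1L)
        if (grepl("^[A-Za-z0-9_.%-]*$", loc))
          return(paste0(names(pfx)[i], ":", loc))
      }
    }
    u
  }, "", USE.NAMES = FALSE)
}

## Predicates registered as object properties: values mapped onto them from
## non-semantic sources become URIs rather than plain literals.
objectProperties <- function() {
  seedTerm(c("includes", "isIncludedIn", "isEntityOf", "hasEntity",
             "isConceptOf", "hasConcept", "isAssociatedTo",
             "hasResource", "isResourceOf", "hasBridge", "isBridgeOf",
             "loadsFrom", "isLoadedBy", "extends"))
}
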