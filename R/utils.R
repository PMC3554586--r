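## Internal helpers shared across modules.

#' @import methods
#' @importFrom stats setNames
#' @importFrom utils head URLencode URLdecode read.csv write.csv
NULL

## Classed condition constructor so callers can distinguish configuration,
## fetch, parse and build failures programmatically.
skbStop <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "seedkb_error", "error")))
}

skbWarn <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "seedkb_warning")))
}

isString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

## RFC 3986 percent-encoding of everything outside the unreserved set.
## Used when item identifiers (e.g. "HGNC:1101") become URI local names.
percentEncode <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), "", USE.NAMES = FALSE)
}

percentDecode <- function(x) {
  vapply(x, utils::URLdecode, "", USE.NAMES = FALSE)
}

## An absolute URI for our purposes: scheme ':' followed by anything.
isAbsoluteURI <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) & !is.na(x)
}

## Strip a UTF-8 byte-order mark if present.
stripBOM <- function(txt) sub("^﻿", "", txt)

readTextFile <- function(path) {
  stripBOM(paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
}

localName <- function(uri, namespace) {
  ifelse(startsWith(uri, namespace), substring(uri, nchar(namespace) + 1L), uri)
}

## Empty statement table: the canonical columnar triple representation.
emptyStatements <- function() {
  data.frame(subject = character(), predicate = character(),
             object = character(), objectKind = character(),
             lang = character(), datatype = character(),
             graph = character(), stringsAsFactors = FALSE)
}

#' Construct a statement table
#'
#' The canonical columnar triple representation used throughout the
#' package: subject and predicate URIs, an object with its term kind
#' ("uri" or "literal"), optional language tag and datatype, and a named
#' graph ("" = default graph). Arguments are recycled to a common length.
#'
#' @param subject,predicate Absolute URIs.
#' @param object Object value (URI or literal lexical form).
#' @param objectKind "uri" or "literal".
#' @param lang,datatype Literal language tag / datatype URI ("" = none).
#' @param graph Named graph ("" = default).
#' @return data.frame of statements.
#' @export
makeStatements <- function(subject, predicate, object,
                           objectKind = "literal", lang = "", datatype = "",
                           graph = "") {
  n <- max(length(subject), length(predicate), length(object))
  if (n == 0L) return(emptyStatements())
  data.frame(subject = rep_len(as.character(subject), n),
             predicate = rep_len(as.character(predicate), n),
             object = rep_len(as.character(object), n),
             objectKind = rep_len(as.character(objectKind), n),
             lang = rep_len(as.character(lang), n),
             datatype = rep_len(as.character(datatype), n),
             graph = rep_len(as.character(graph), n),
             stringsAsFactors = FALSE)
}

statementKey <- function(st) {
  paste(st$subject, st$predicate, st$object, st$objectKind, st$lang,
        st$datatype, st$graph, sep = "\r")
}

dedupStatements <- function(st) st[!duplicated(statementKey(st)), , drop = FALSE]
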