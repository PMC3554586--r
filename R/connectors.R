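## Connectors: fetch raw content from a resource URI and evaluate selectors
## against it, yielding the model-independent RecordSet — the abstraction
## layer between heterogeneous sources and triplification.

newRecordSet <- function(records, kinds = NULL, sourceUri = "",
                         skips = NULL) {
  if (is.null(kinds))
    kinds <- lapply(records, function(r) lapply(r, function(v)
      rep("literal", length(v))))
  if (is.null(skips))
    skips <- data.frame(row = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  new("RecordSet", records = records, kinds = kinds, sourceUri = sourceUri,
      skips = skips)
}

#' Number of records in a RecordSet
#' @param rs A \linkS4class{RecordSet}.
#' @return Integer.
#' @export
recordCount <- function(rs) length(rs@records)

#' Substitute the #replace# token in a URI or URL template
#' @param template Template string.
#' @param id Replacement value.
#' @return Template with every occurrence of the token substituted.
#' @export
resolveTemplate <- function(template, id) {
  gsub("#replace#", id, template, fixed = TRUE)
}

#' Build a FetchSpec from a resource and an optional item identifier
#' @param resource A \linkS4class{ResourceDef}.
#' @param id Identifier substituted for \code{#replace#} (complete method).
#' @return A \linkS4class{FetchSpec}.
#' @export
fetchSpec <- function(resource, id = NULL) {
  uri <- resource@endpoint
  if (!is.null(id)) uri <- resolveTemplate(uri, id)
  query <- unlist(resource@extras[["seed:queryText"]]) %||% NA_character_
  new("FetchSpec", uri = uri, kind = resource@kind,
      queryText = if (length(query)) query[[1L]] else NA_character_)
}

## --- endpoint registry ----------------------------------------------------

#' In-process SPARQL endpoint registry
#'
#' Maps endpoint URIs to \linkS4class{KnowledgeBase} objects so that SPARQL
#' connectors and SERVICE clauses resolve without network access. Multiple
#' registered graphs emulate a federation of independent seeds.
#'
#' @return An endpoint registry (environment).
#' @export
EndpointRegistry <- function() {
  new.env(parent = emptyenv())
}

#' @describeIn EndpointRegistry Register a knowledge base under a URI.
#' @param registry An endpoint registry.
#' @param uri Endpoint URI.
#' @param kb A \linkS4class{KnowledgeBase}.
#' @export
registerEndpoint <- function(registry, uri, kb) {
  assign(uri, kb, envir = registry)
  invisible(uri)
}

#' @describeIn EndpointRegistry Remove an endpoint registration.
#' @export
releaseEndpoint <- function(registry, uri) {
  if (exists(uri, envir = registry, inherits = FALSE))
    rm(list = uri, envir = registry)
  invisible(NULL)
}

#' @describeIn EndpointRegistry Resolve a URI to its knowledge base;
#'   an unknown endpoint raises a fetch error naming the URI.
#' @export
resolveEndpoint <- function(registry, uri) {
  if (is.null(registry) || !exists(uri, envir = registry, inherits = FALSE))
    skbStop("seedkb_fetch_error",
            sprintf("SPARQL endpoint unreachable: <%s>", uri), uri = uri)
  get(uri, envir = registry, inherits = FALSE)
}

## --- embedded SQL ---------------------------------------------------------

pythonBin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p))
    skbStop("seedkb_fetch_error", "no python interpreter found for the SQL bridge")
  p
}

sqlBridgeScript <- function() {
  path <- file.path(tempdir(), "seedkb-sql-bridge.py")
  if (!file.exists(path)) {
    writeLines(c(
      "import sqlite3, json, sys",
      "db, qfile, mode = sys.argv[1], sys.argv[2], sys.argv[3]",
      "q = open(qfile).read()",
      "con = sqlite3.connect(db)",
      "if mode == 'script':",
      "    con.executescript(q)",
      "    con.commit()",
      "    print(json.dumps({'ok': True}))",
      "else:",
      "    cur = con.execute(q)",
      "    cols = [d[0] for d in cur.description] if cur.description else []",
      "    rows = [list(r) for r in cur.fetchall()]",
      "    print(json.dumps({'columns': cols, 'rows': rows}))",
      "con.close()"), path)
  }
  path
}

sqlitePathFromURI <- function(uri) {
  if (startsWith(uri, "sqlite:///")) return(substring(uri, 11L))
  if (startsWith(uri, "sqlite:")) return(sub("^sqlite:/*", "/", uri))
  if (startsWith(uri, "file://")) return(sub("^file://", "", uri))
  uri
}

#' Run a SQL query against an embedded SQLite database
#'
#' The relational connection URI has the form \code{sqlite:///path/to.db}.
#' Execution is delegated to the system SQLite engine (through the Python
#' standard library shipped in the same environment).
#'
#' @param uri Connection URI or database file path.
#' @param sql SQL text.
#' @param mode "query" (returns a result table) or "script" (DDL/DML).
#' @return data.frame of the result table (query mode); NULL (script mode).
#' @export
sqlQuery <- function(uri, sql, mode = c("query", "script")) {
  mode <- match.arg(mode)
  db <- sqlitePathFromURI(uri)
  if (mode == "query" && !file.exists(db))
    skbStop("seedkb_fetch_error",
            sprintf("SQL database unreachable: <%s>", uri), uri = uri)
  qfile <- tempfile(fileext = ".sql")
  on.exit(unlink(qfile))
  writeLines(sql, qfile)
  out <- suppressWarnings(
    system2(pythonBin(), c(sqlBridgeScript(), shQuote(db), shQuote(qfile), mode),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L)
    skbStop("seedkb_fetch_error",
            sprintf("SQL execution failed for <%s>: %s", uri,
                    paste(out, collapse = " ")), uri = uri)
  if (mode == "script") return(invisible(NULL))
  js <- jsonlite::fromJSON(paste(out, collapse = "\n"), simplifyVector = FALSE)
  cols <- unlist(js$columns)
  rows <- js$rows
  df <- as.data.frame(stats::setNames(
    lapply(seq_along(cols), function(j)
      vapply(rows, function(r) {
        v <- r[[j]]
        if (is.null(v)) NA_character_ else as.character(v)
      }, "")),
    cols), stringsAsFactors = FALSE, check.names = FALSE, optional = TRUE)
  df
}

## --- fetch ----------------------------------------------------------------

fileFromURI <- function(uri) {
  if (startsWith(uri, "file://")) utils::URLdecode(sub("^file://", "", uri))
  else uri
}

#' Fetch raw content for a resolved source address
#'
#' csv/xml specs return the decoded text of the document (file and file://
#' URIs; http(s) attempted over a connection); sql specs return a result
#' table; sparql specs return a SELECT result from the registered endpoint.
#' Per-run caching makes per-item completes replayable.
#'
#' @param spec A \linkS4class{FetchSpec}.
#' @param registry Endpoint registry for sparql specs.
#' @param cache Optional environment caching fetches within a build run.
#' @return Text (csv/xml), data.frame (sql) or SELECT result (sparql).
#' @export
fetchSource <- function(spec, registry = NULL, cache = NULL) {
  key <- paste0(spec@kind, "\r", spec@uri, "\r", spec@queryText)
  if (!is.null(cache) && exists(key, envir = cache, inherits = FALSE))
    return(get(key, envir = cache, inherits = FALSE))
  out <- switch(spec@kind,
    csv = ,
    xml = {
      uri <- spec@uri
      if (grepl("^https?://", uri)) {
        txt <- tryCatch({
          con <- url(uri, open = "rb")
          on.exit(close(con), add = TRUE)
          paste(readLines(con, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
        }, error = function(e)
          skbStop("seedkb_fetch_error",
                  sprintf("unreachable URI <%s>: %s", uri, conditionMessage(e)),
                  uri = uri))
        stripBOM(txt)
      } else {
        path <- fileFromURI(uri)
        if (!file.exists(path))
          skbStop("seedkb_fetch_error",
                  sprintf("unreachable URI <%s>: no such file", uri), uri = uri)
        readTextFile(path)
      }
    },
    sql = {
      if (is.na(spec@queryText))
        skbStop("seedkb_config_error",
                sprintf("sql resource <%s> lacks a query", spec@uri))
      sqlQuery(spec@uri, spec@queryText)
    },
    sparql = {
      if (is.na(spec@queryText))
        skbStop("seedkb_config_error",
                sprintf("sparql resource <%s> lacks a query", spec@uri))
      kb <- resolveEndpoint(registry, spec@uri)
      res <- sparqlQuery(kb, spec@queryText, registry)
      if (res$type != "select")
        skbStop("seedkb_config_error", "sparql resource query must be a SELECT")
      res
    },
    skbStop("seedkb_config_error",
            sprintf("unknown connector kind '%s'", spec@kind)))
  if (!is.null(cache)) assign(key, out, envir = cache)
  out
}

## --- selector evaluation --------------------------------------------------

## RFC 4180-ish line splitter: comma-separated, double-quote quoting with
## "" escapes. Quoted newlines are not supported (sources are line-based).
csvSplitLine <- function(line, sep = ",") {
  out <- character(); field <- ""; inq <- FALSE
  chars <- strsplit(line, "")[[1L]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (inq) {
      if (ch == "\"") {
        if (i < n && chars[[i + 1L]] == "\"") { field <- paste0(field, "\""); i <- i + 1L }
        else inq <- FALSE
      } else field <- paste0(field, ch)
    } else {
      if (ch == "\"") inq <- TRUE
      else if (ch == sep) { out <- c(out, field); field <- "" }
      else field <- paste0(field, ch)
    }
    i <- i + 1L
  }
  c(out, field)
}

#' Evaluate CSV selectors
#'
#' One record per data row; each selector's value is the cell at its
#' 0-based column index. Rows narrower than a selector's index are skipped
#' and reported, not silently dropped.
#'
#' @param content CSV text.
#' @param selectors List of \linkS4class{Selector} with integer queries.
#' @param header Treat the first row as a header (excluded from records).
#' @param sep Field separator.
#' @param sourceUri Recorded provenance URI.
#' @return A \linkS4class{RecordSet}.
#' @export
selectCSV <- function(content, selectors, header = TRUE, sep = ",",
                      sourceUri = "") {
  idx <- vapply(selectors, function(s) suppressWarnings(as.integer(s@query)), 1L)
  if (anyNA(idx) || any(idx < 0L))
    skbStop("seedkb_config_error",
            paste("CSV selector query is not a column index >= 0:",
                  paste(vapply(selectors[is.na(idx) | idx < 0L], slot, "", "key"),
                        collapse = ", ")))
  handles <- vapply(selectors, slot, "", "key")
  lines <- strsplit(content, "\r?\n")[[1L]]
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1L]
  records <- list(); skips <- list()
  for (i in seq_along(lines)) {
    cells <- csvSplitLine(lines[[i]], sep)
    if (any(idx >= length(cells))) {
      skips[[length(skips) + 1L]] <-
        data.frame(row = i, reason = sprintf(
          "row has %d columns, selector needs index %d",
          length(cells), max(idx)), stringsAsFactors = FALSE)
      next
    }
    rec <- lapply(idx, function(j) {
      v <- cells[[j + 1L]]
      if (nzchar(v)) v else character()
    })
    names(rec) <- handles
    records[[length(records) + 1L]] <- rec
  }
  newRecordSet(records, sourceUri = sourceUri,
               skips = if (length(skips)) do.call(rbind, skips) else NULL)
}

#' Evaluate XML selectors
#'
#' One record per node matched by \code{recordPath}; selector queries are
#' XPath expressions evaluated relative to each record node, multi-match
#' selectors yielding multiple values in document order.
#'
#' @param content XML text.
#' @param selectors List of \linkS4class{Selector} with XPath queries.
#' @param recordPath XPath selecting the record nodes; default the document
#'   root (a single record).
#' @param sourceUri Recorded provenance URI.
#' @return A \linkS4class{RecordSet}.
#' @export
selectXML <- function(content, selectors, recordPath = "/*", sourceUri = "") {
  doc <- tryCatch(xml2::read_xml(content),
                  error = function(e)
                    skbStop("seedkb_parse_error",
                            paste("malformed XML:", conditionMessage(e))))
  ## xml2 reports an invalid XPath as a warning with an empty result; both
  ## failure modes become configuration errors here
  findAll <- function(node, xpath, what) {
    withCallingHandlers(
      tryCatch(xml2::xml_find_all(node, xpath),
               error = function(e)
                 skbStop("seedkb_config_error",
                         sprintf("invalid XPath in %s: %s", what,
                                 conditionMessage(e)))),
      warning = function(w) {
        skbStop("seedkb_config_error",
                sprintf("invalid XPath in %s: %s", what, conditionMessage(w)))
      })
  }
  nodes <- findAll(doc, recordPath, sprintf("record path '%s'", recordPath))
  handles <- vapply(selectors, slot, "", "key")
  records <- lapply(seq_along(nodes), function(i) {
    rec <- lapply(selectors, function(sel) {
      hits <- findAll(nodes[[i]], sel@query,
                      sprintf("selector '%s'", sel@key))
      if (inherits(hits, "xml_nodeset")) xml2::xml_text(hits)
      else as.character(hits)
    })
    names(rec) <- handles
    rec
  })
  newRecordSet(records, sourceUri = sourceUri)
}

#' Evaluate SQL selectors over a result table
#'
#' One record per row; values are taken by result-column name. NULL cells
#' become empty value lists, never the string "NA".
#'
#' @param table data.frame as returned by \code{\link{sqlQuery}}.
#' @param selectors List of \linkS4class{Selector} with column-name queries.
#' @param sourceUri Recorded provenance URI.
#' @return A \linkS4class{RecordSet}.
#' @export
selectSQL <- function(table, selectors, sourceUri = "") {
  handles <- vapply(selectors, slot, "", "key")
  cols <- vapply(selectors, slot, "", "query")
  missing <- setdiff(cols, names(table))
  if (length(missing))
    skbStop("seedkb_config_error",
            paste("unknown SQL result column(s):", paste(missing, collapse = ", ")))
  records <- lapply(seq_len(nrow(table)), function(i) {
    rec <- lapply(cols, function(cn) {
      v <- table[[cn]][i]
      if (is.na(v)) character() else as.character(v)
    })
    names(rec) <- handles
    rec
  })
  newRecordSet(records, sourceUri = sourceUri)
}

#' Evaluate SPARQL selectors over a SELECT result
#'
#' One record per solution; selector queries name result variables. Unbound
#' variables become empty value lists. URI and literal bindings are both
#' rendered to their lexical form with the term kind retained alongside.
#'
#' @param results SELECT result from \code{\link{sparqlQuery}}.
#' @param selectors List of \linkS4class{Selector} with variable-name
#'   queries.
#' @param sourceUri Recorded provenance URI.
#' @return A \linkS4class{RecordSet}.
#' @export
selectSPARQL <- function(results, selectors, sourceUri = "") {
  handles <- vapply(selectors, slot, "", "key")
  vars <- sub("^[?$]", "", vapply(selectors, slot, "", "query"))
  missing <- setdiff(vars, results$vars)
  if (length(missing))
    skbStop("seedkb_config_error",
            paste("unknown SPARQL result variable(s):",
                  paste(missing, collapse = ", ")))
  sol <- results$solutions
  records <- list(); kinds <- list()
  for (i in seq_len(nrow(sol))) {
    rec <- list(); knd <- list()
    for (j in seq_along(vars)) {
      enc <- sol[[vars[[j]]]][i]
      if (is.na(enc)) {
        rec[[handles[[j]]]] <- character()
        knd[[handles[[j]]]] <- character()
      } else {
        t <- decTerm(enc)
        rec[[handles[[j]]]] <- t$value
        knd[[handles[[j]]]] <- t$kind
      }
    }
    records[[length(records) + 1L]] <- rec
    kinds[[length(kinds) + 1L]] <- knd
  }
  newRecordSet(records, kinds = kinds, sourceUri = sourceUri)
}

#' Fetch a resource and evaluate its selectors
#'
#' Dispatches on the resource's connector kind, honouring the open
#' properties \code{seed:header} (CSV header flag, default true),
#' \code{seed:separator} and \code{seed:recordPath}.
#'
#' @param resource A \linkS4class{ResourceDef}.
#' @param id Optional item identifier for \code{#replace#} substitution.
#' @param registry Endpoint registry (sparql kind).
#' @param cache Optional per-run fetch cache.
#' @return A \linkS4class{RecordSet}.
#' @export
selectRecords <- function(resource, id = NULL, registry = NULL, cache = NULL) {
  spec <- fetchSpec(resource, id)
  raw <- fetchSource(spec, registry, cache)
  extra1 <- function(name, default) {
    v <- unlist(resource@extras[[name]])
    if (length(v)) v[[1L]] else default
  }
  switch(resource@kind,
    csv = selectCSV(raw, resource@selectors,
                    header = !identical(tolower(extra1("seed:header", "true")), "false"),
                    sep = extra1("seed:separator", ","),
                    sourceUri = spec@uri),
    xml = selectXML(raw, resource@selectors,
                    recordPath = extra1("seed:recordPath", "/*"),
                    sourceUri = spec@uri),
    sql = selectSQL(raw, resource@selectors, sourceUri = spec@uri),
    sparql = selectSPARQL(raw, resource@selectors, sourceUri = spec@uri))
}
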