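## SPARQL 1.1 subset engine.
##
## Read-only SELECT / ASK / CONSTRUCT / DESCRIBE over a KnowledgeBase:
## basic graph patterns joined left-to-right, OPTIONAL (left join),
## FILTER (=, !=, regex, bound), and SERVICE clauses resolved through an
## endpoint registry with nested binding propagation in clause order.
## Update forms are rejected before execution.

## --- encoded terms --------------------------------------------------------
## Solutions are data.frames of encoded term strings so joins are plain
## string equality: "<uri>" for URIs, '"lex"', '"lex"@lang', '"lex"^^<dt>'
## for literals, NA for unbound.

encTerm <- function(value, kind, lang = "", datatype = "") {
  ifelse(kind == "uri", paste0("<", value, ">"),
         paste0("\"", escapeTurtle(value), "\"",
                ifelse(nzchar(lang), paste0("@", lang), ""),
                ifelse(nzchar(datatype) & !nzchar(lang),
                       paste0("^^<", datatype, ">"), "")))
}

decTerm <- function(enc) {
  if (is.na(enc)) return(NULL)
  if (startsWith(enc, "<"))
    return(list(value = substr(enc, 2L, nchar(enc) - 1L), kind = "uri",
                lang = "", datatype = ""))
  m <- regmatches(enc, regexec('^"((?:[^"\\\\]|\\\\.)*)"(?:@([A-Za-z-]+)|\\^\\^<([^>]*)>)?$',
                               enc))[[1]]
  if (!length(m))
    skbStop("seedkb_internal_error", paste("bad encoded term:", enc))
  list(value = unescapeTurtle(m[2]), kind = "literal",
       lang = m[3] %||% "", datatype = m[4] %||% "")
}

encodeObjects <- function(st) encTerm(st$object, st$objectKind, st$lang, st$datatype)

## --- tokenizer ------------------------------------------------------------

SPARQL_KEYWORDS <- c("SELECT", "ASK", "CONSTRUCT", "DESCRIBE", "WHERE",
                     "PREFIX", "BASE", "DISTINCT", "REDUCED", "FILTER",
                     "OPTIONAL", "SERVICE", "UNION", "ORDER", "BY", "ASC",
                     "DESC", "LIMIT", "OFFSET", "REGEX", "BOUND", "STR",
                     "FROM", "NAMED")

SPARQL_UPDATE_KEYWORDS <- c("INSERT", "DELETE", "LOAD", "CLEAR", "CREATE",
                            "DROP", "MOVE", "COPY", "ADD", "WITH", "MODIFY")

sparqlTokenize <- function(text) {
  tokens <- list(); pos <- 1L; n <- nchar(text); line <- 1L
  while (pos <= n) {
    rest <- substring(text, pos)
    ws <- regmatches(rest, regexpr("^([ \t\r\n]+|#[^\n]*)", rest))
    if (length(ws)) {
      line <- line + lengths(regmatches(ws, gregexpr("\n", ws, fixed = TRUE)))
      pos <- pos + nchar(ws); next
    }
    matched <- NULL; type <- NULL
    pats <- c(iri = "^<[^<>\"{}|^`\\\\[:space:]]*>",
              string = "^\"([^\"\\\\]|\\\\.)*\"",
              var = "^[?$][A-Za-z_][A-Za-z0-9_]*",
              dtype_sep = "^\\^\\^",
              lang = "^@[A-Za-z]+(-[A-Za-z0-9]+)*",
              neq = "^!=",
              word = "^[A-Za-z][A-Za-z0-9_]*",
              pname = "^([A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_][A-Za-z0-9_.%-]*|^([A-Za-z_][A-Za-z0-9_.-]*)?:",
              number = "^[+-]?[0-9]+(\\.[0-9]+)?",
              punct = "^[{}().;,*=]")
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m)) { matched <- m; type <- ty; break }
    }
    if (is.null(matched))
      skbStop("seedkb_query_error",
              sprintf("SPARQL parse error at line %d near '%s'",
                      line, substr(rest, 1L, 30L)))
    ## distinguish keywords from prefixed-name prefixes: 'word' followed by
    ## ':' is part of a pname
    if (type == "word") {
      after <- substring(text, pos + nchar(matched), pos + nchar(matched))
      if (identical(after, ":")) {
        m2 <- regmatches(rest, regexpr(pats[["pname"]], rest, perl = TRUE))
        matched <- m2; type <- "pname"
      }
    }
    tokens[[length(tokens) + 1L]] <- list(type = type, text = matched, line = line)
    line <- line + lengths(regmatches(matched, gregexpr("\n", matched, fixed = TRUE)))
    pos <- pos + nchar(matched)
  }
  tokens
}

## --- parser ---------------------------------------------------------------

#' Parse a SPARQL query
#'
#' @param query SPARQL 1.1 query text (SELECT, ASK, CONSTRUCT or DESCRIBE;
#'   update forms are rejected).
#' @return An abstract syntax tree (list), internal to the engine.
#' @export
parseSPARQL <- function(query) {
  toks <- sparqlTokenize(query)
  i <- 1L
  prefixes <- basePrefixes()
  peek <- function(k = 0L) if (i + k <= length(toks)) toks[[i + k]] else NULL
  take <- function() { t <- toks[[i]]; i <<- i + 1L; t }
  fail <- function(msg, t = peek()) {
    skbStop("seedkb_query_error",
            sprintf("SPARQL parse error%s: %s",
                    if (!is.null(t)) sprintf(" at line %d ('%s')", t$line, t$text) else "",
                    msg))
  }
  isWord <- function(t, w) !is.null(t) && t$type == "word" && toupper(t$text) %in% w
  expectWord <- function(w) { t <- peek(); if (!isWord(t, w)) fail(paste("expected", w)); take() }
  expectPunct <- function(p) {
    t <- peek()
    if (is.null(t) || t$type != "punct" || t$text != p) fail(paste0("expected '", p, "'"))
    take()
  }
  parseTermToken <- function() {
    t <- take()
    if (t$type == "var") return(list(type = "var", name = substring(t$text, 2L)))
    if (t$type == "iri")
      return(list(type = "term", enc = paste0("<", substr(t$text, 2L, nchar(t$text) - 1L), ">")))
    if (t$type == "pname") {
      u <- expandCURIE(t$text, prefixes)
      return(list(type = "term", enc = paste0("<", u, ">")))
    }
    if (t$type == "word" && t$text == "a")
      return(list(type = "term", enc = paste0("<", rdfType(), ">")))
    if (t$type == "string") {
      val <- substr(t$text, 2L, nchar(t$text) - 1L)
      lang <- ""; dt <- ""
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "lang") lang <- substring(take()$text, 2L)
      else if (!is.null(nxt) && nxt$type == "dtype_sep") {
        take()
        dtTok <- take()
        dt <- if (dtTok$type == "iri") substr(dtTok$text, 2L, nchar(dtTok$text) - 1L)
              else expandCURIE(dtTok$text, prefixes)
      }
      return(list(type = "term",
                  enc = encTerm(unescapeTurtle(val), "literal", lang, dt)))
    }
    if (t$type == "number") {
      dt <- paste0(XSD_NS, if (grepl(".", t$text, fixed = TRUE)) "decimal" else "integer")
      return(list(type = "term", enc = encTerm(t$text, "literal", "", dt)))
    }
    if (t$type == "word" && tolower(t$text) %in% c("true", "false"))
      return(list(type = "term",
                  enc = encTerm(tolower(t$text), "literal", "", paste0(XSD_NS, "boolean"))))
    fail("expected RDF term or variable", t)
  }
  parseTriplesBlock <- function() {
    patterns <- list()
    subj <- parseTermToken()
    repeat {
      pred <- parseTermToken()
      repeat {
        obj <- parseTermToken()
        patterns[[length(patterns) + 1L]] <- list(s = subj, p = pred, o = obj)
        t <- peek()
        if (!is.null(t) && t$type == "punct" && t$text == ",") { take(); next }
        break
      }
      t <- peek()
      if (!is.null(t) && t$type == "punct" && t$text == ";") {
        take()
        nxt <- peek()
        if (!is.null(nxt) && nxt$type == "punct" && nxt$text %in% c(".", "}")) next
        next
      }
      break
    }
    t <- peek()
    if (!is.null(t) && t$type == "punct" && t$text == ".") take()
    patterns
  }
  parseRegexCall <- function() {
    expectPunct("(")
    v <- parseTermToken()
    expectPunct(",")
    patTok <- take()
    if (patTok$type != "string") fail("regex pattern must be a string", patTok)
    flags <- ""
    if (!is.null(peek()) && peek()$type == "punct" && peek()$text == ",") {
      take(); fTok <- take(); flags <- substr(fTok$text, 2L, nchar(fTok$text) - 1L)
    }
    expectPunct(")")
    list(kind = "regex", var = v,
         pattern = substr(patTok$text, 2L, nchar(patTok$text) - 1L),
         flags = flags)
  }
  parseFilter <- function() {
    ## FILTER regex(...) / FILTER bound(...) may omit the outer parentheses
    t <- peek()
    if (isWord(t, "REGEX")) { take(); return(parseRegexCall()) }
    if (isWord(t, "BOUND")) {
      take(); expectPunct("(")
      v <- parseTermToken()
      expectPunct(")")
      return(list(kind = "bound", var = v))
    }
    expectPunct("(")
    t <- peek()
    if (isWord(t, "REGEX")) {
      take()
      f <- parseRegexCall()
      expectPunct(")")
      return(f)
    }
    if (isWord(t, "BOUND")) {
      take(); expectPunct("(")
      v <- parseTermToken()
      expectPunct(")"); expectPunct(")")
      return(list(kind = "bound", var = v))
    }
    lhs <- parseTermToken()
    opTok <- take()
    op <- if (opTok$type == "neq") "!=" else if (opTok$text == "=") "=" else
      fail("expected '=' or '!=' in FILTER", opTok)
    rhs <- parseTermToken()
    expectPunct(")")
    list(kind = "cmp", op = op, lhs = lhs, rhs = rhs)
  }
  parseGroup <- function() {
    expectPunct("{")
    elements <- list()
    repeat {
      t <- peek()
      if (is.null(t)) fail("unterminated group pattern")
      if (t$type == "punct" && t$text == "}") { take(); break }
      if (t$type == "punct" && t$text == ".") { take(); next }
      if (isWord(t, "FILTER")) {
        take()
        elements[[length(elements) + 1L]] <- c(list(elem = "filter"), parseFilter())
      } else if (isWord(t, "OPTIONAL")) {
        take()
        elements[[length(elements) + 1L]] <- list(elem = "optional", group = parseGroup())
      } else if (isWord(t, "SERVICE")) {
        take()
        ep <- parseTermToken()
        if (ep$type != "term") fail("SERVICE endpoint must be an IRI")
        elements[[length(elements) + 1L]] <- list(elem = "service", endpoint = ep$enc,
                                                  group = parseGroup())
      } else {
        elements[[length(elements) + 1L]] <- list(elem = "bgp",
                                                  patterns = parseTriplesBlock())
      }
    }
    list(elements = elements)
  }
  ## prologue
  repeat {
    t <- peek()
    if (isWord(t, "PREFIX")) {
      take()
      pn <- take()
      if (pn$type != "pname") fail("expected prefix name after PREFIX", pn)
      pfx <- sub(":.*$", "", pn$text)
      iri <- take()
      if (iri$type != "iri") fail("expected IRI after prefix name", iri)
      prefixes[[pfx]] <- substr(iri$text, 2L, nchar(iri$text) - 1L)
    } else if (isWord(t, "BASE")) {
      take(); take()
    } else break
  }
  t <- peek()
  if (isWord(t, SPARQL_UPDATE_KEYWORDS))
    skbStop("seedkb_query_error",
            sprintf("update form '%s' rejected: this endpoint is read-only",
                    toupper(t$text)))
  if (!isWord(t, c("SELECT", "ASK", "CONSTRUCT", "DESCRIBE")))
    fail("expected SELECT, ASK, CONSTRUCT or DESCRIBE")
  form <- toupper(take()$text)
  ast <- list(form = form, prefixes = prefixes, distinct = FALSE,
              vars = NULL, template = NULL, describeTerms = list(),
              group = NULL, orderBy = NULL, orderDesc = FALSE,
              limit = NA_integer_, offset = 0L)
  if (form == "SELECT") {
    t <- peek()
    if (isWord(t, c("DISTINCT", "REDUCED"))) { take(); ast$distinct <- TRUE }
    vars <- character()
    repeat {
      t <- peek()
      if (!is.null(t) && t$type == "var") { vars <- c(vars, substring(take()$text, 2L)); next }
      if (!is.null(t) && t$type == "punct" && t$text == "*") { take(); vars <- "*"; }
      break
    }
    if (!length(vars)) fail("SELECT needs projection variables or *")
    ast$vars <- vars
    if (isWord(peek(), "WHERE")) take()
    ast$group <- parseGroup()
  } else if (form == "ASK") {
    if (isWord(peek(), "WHERE")) take()
    ast$group <- parseGroup()
  } else if (form == "CONSTRUCT") {
    expectPunct("{")
    tmpl <- list()
    while (!(peek()$type == "punct" && peek()$text == "}"))
      tmpl <- c(tmpl, parseTriplesBlock())
    expectPunct("}")
    ast$template <- tmpl
    expectWord("WHERE")
    ast$group <- parseGroup()
  } else { # DESCRIBE
    repeat {
      t <- peek()
      if (is.null(t) || isWord(t, "WHERE") ||
          (t$type == "punct" && t$text == "{")) break
      ast$describeTerms[[length(ast$describeTerms) + 1L]] <- parseTermToken()
    }
    if (isWord(peek(), "WHERE")) take()
    if (!is.null(peek()) && peek()$type == "punct" && peek()$text == "{")
      ast$group <- parseGroup()
  }
  ## solution modifiers
  repeat {
    t <- peek()
    if (isWord(t, "ORDER")) {
      take(); expectWord("BY")
      if (isWord(peek(), c("ASC", "DESC"))) {
        ast$orderDesc <- toupper(take()$text) == "DESC"
        expectPunct("(")
        ast$orderBy <- substring(take()$text, 2L)
        expectPunct(")")
      } else {
        v <- take()
        if (v$type != "var") fail("ORDER BY expects a variable", v)
        ast$orderBy <- substring(v$text, 2L)
      }
    } else if (isWord(t, "LIMIT")) {
      take(); ast$limit <- as.integer(take()$text)
    } else if (isWord(t, "OFFSET")) {
      take(); ast$offset <- as.integer(take()$text)
    } else break
  }
  if (!is.null(peek())) fail("trailing tokens after query")
  ast
}

## --- evaluation -----------------------------------------------------------

unitSolutions <- function() data.frame(row.names = 1L)[, 0, drop = FALSE]
noSolutions <- function() data.frame()[0, 0, drop = FALSE]

joinSolutions <- function(a, b, left = FALSE) {
  if (nrow(a) == 0L && !left) return(a[0, union(names(a), names(b)), drop = FALSE])
  common <- intersect(names(a), names(b))
  a$..ra <- seq_len(nrow(a))
  if (length(common) == 0L) {
    if (nrow(b) == 0L) {
      out <- if (left) a else cbind(a[0, , drop = FALSE])
      out$..ra <- NULL
      for (v in names(b)) out[[v]] <- character(nrow(out))[seq_len(nrow(out))]
      return(out)
    }
    idx <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
    out <- cbind(a[idx$ia, , drop = FALSE], b[idx$ib, , drop = FALSE])
    out$..ra <- NULL
    row.names(out) <- NULL
    return(out)
  }
  m <- merge(a, b, by = common, all.x = left, sort = FALSE)
  m <- m[order(m$..ra), , drop = FALSE]
  m$..ra <- NULL
  row.names(m) <- NULL
  m
}

matchPattern <- function(kb, pat, solutions) {
  st <- kbStatements(kb)
  stEnc <- data.frame(s = paste0("<", st$subject, ">"),
                      p = paste0("<", st$predicate, ">"),
                      o = encodeObjects(st), stringsAsFactors = FALSE)
  cols <- character(); sel <- rep(TRUE, nrow(stEnc))
  for (pos in c("s", "p", "o")) {
    el <- pat[[pos]]
    if (el$type == "term") {
      sel <- sel & stEnc[[pos]] == el$enc
    } else {
      cols[pos] <- el$name
    }
  }
  rows <- stEnc[sel, , drop = FALSE]
  if (!length(cols)) {
    b <- if (nrow(rows)) unitSolutions() else noSolutions()
  } else {
    b <- stats::setNames(rows[names(cols)], unname(cols))
    ## a variable repeated inside one pattern must bind consistently
    dupVars <- unique(cols[duplicated(cols)])
    if (length(dupVars)) {
      positions <- split(names(cols), unname(cols))
      keep <- rep(TRUE, nrow(rows))
      for (v in dupVars) {
        ps <- positions[[v]]
        for (k in seq_along(ps)[-1])
          keep <- keep & rows[[ps[1]]] == rows[[ps[k]]]
      }
      b <- b[keep, !duplicated(names(b)), drop = FALSE]
    }
    row.names(b) <- NULL
  }
  joinSolutions(solutions, b)
}

applyFilter <- function(f, solutions) {
  if (!nrow(solutions)) return(solutions)
  valOf <- function(el) {
    if (el$type == "var") {
      if (!el$name %in% names(solutions)) return(rep(NA_character_, nrow(solutions)))
      solutions[[el$name]]
    } else rep(el$enc, nrow(solutions))
  }
  keep <- switch(f$kind,
    cmp = {
      l <- valOf(f$lhs); r <- valOf(f$rhs)
      eq <- !is.na(l) & !is.na(r) & l == r
      if (f$op == "=") eq else (!is.na(l) & !is.na(r) & l != r)
    },
    regex = {
      v <- valOf(f$var)
      lex <- vapply(v, function(e) if (is.na(e)) NA_character_ else decTerm(e)$value, "")
      !is.na(lex) & grepl(f$pattern, lex,
                          ignore.case = grepl("i", f$flags, fixed = TRUE))
    },
    bound = !is.na(valOf(f$var)))
  solutions[keep, , drop = FALSE]
}

evalGroup <- function(group, kb, registry, solutions) {
  filters <- list()
  for (el in group$elements) {
    if (el$elem == "bgp") {
      for (pat in el$patterns) solutions <- matchPattern(kb, pat, solutions)
    } else if (el$elem == "optional") {
      right <- evalGroup(el$group, kb, registry, unitSolutions())
      solutions <- joinSolutions(solutions, right, left = TRUE)
    } else if (el$elem == "service") {
      uri <- substr(el$endpoint, 2L, nchar(el$endpoint) - 1L)
      epKb <- resolveEndpoint(registry, uri)
      ## binding propagation: evaluate the service group once per distinct
      ## relevant binding is equivalent here to a full evaluation + join
      right <- evalGroup(el$group, epKb, registry, unitSolutions())
      solutions <- joinSolutions(solutions, right)
    } else if (el$elem == "filter") {
      filters[[length(filters) + 1L]] <- el
    }
  }
  for (f in filters) solutions <- applyFilter(f, solutions)
  solutions
}

groupVars <- function(group) {
  vars <- character()
  for (el in group$elements) {
    if (el$elem == "bgp") {
      for (pat in el$patterns)
        for (pos in c("s", "p", "o"))
          if (pat[[pos]]$type == "var") vars <- c(vars, pat[[pos]]$name)
    } else if (el$elem %in% c("optional", "service")) {
      vars <- c(vars, groupVars(el$group))
    }
  }
  unique(vars)
}

#' Execute a SPARQL query against a knowledge base
#'
#' @param kb A \linkS4class{KnowledgeBase}.
#' @param query SPARQL query text, or a parsed AST from
#'   \code{\link{parseSPARQL}}.
#' @param registry Endpoint registry used to resolve SERVICE clauses (see
#'   \code{\link{EndpointRegistry}}); NULL when the query is local-only.
#' @return For SELECT: list(type="select", vars, solutions) where solutions
#'   is a data.frame of encoded terms (NA = unbound). For ASK:
#'   list(type="ask", value). For CONSTRUCT/DESCRIBE: list(type="graph",
#'   statements).
#' @export
sparqlQuery <- function(kb, query, registry = NULL) {
  ast <- if (is.character(query)) parseSPARQL(query) else query
  if (ast$form == "ASK") {
    sol <- evalGroup(ast$group, kb, registry, unitSolutions())
    return(list(type = "ask", value = nrow(sol) > 0L))
  }
  if (ast$form == "DESCRIBE") {
    out <- emptyStatements()
    for (t in ast$describeTerms) {
      if (t$type != "term") next
      uri <- decTerm(t$enc)$value
      out <- rbind(out, matchTriples(kb, subject = uri))
    }
    return(list(type = "graph", statements = dedupStatements(out)))
  }
  sol <- evalGroup(ast$group, kb, registry, unitSolutions())
  if (ast$form == "CONSTRUCT") {
    out <- list()
    for (pat in ast$template) {
      getEnc <- function(el) {
        if (el$type == "term") rep(el$enc, nrow(sol))
        else if (el$name %in% names(sol)) sol[[el$name]]
        else rep(NA_character_, nrow(sol))
      }
      s <- getEnc(pat$s); p <- getEnc(pat$p); o <- getEnc(pat$o)
      ok <- !is.na(s) & !is.na(p) & !is.na(o) &
        startsWith(ifelse(is.na(s), "", s), "<") &
        startsWith(ifelse(is.na(p), "", p), "<")
      if (!any(ok)) next
      od <- lapply(o[ok], decTerm)
      out[[length(out) + 1L]] <- makeStatements(
        subject = substr(s[ok], 2L, nchar(s[ok]) - 1L),
        predicate = substr(p[ok], 2L, nchar(p[ok]) - 1L),
        object = vapply(od, `[[`, "", "value"),
        objectKind = vapply(od, `[[`, "", "kind"),
        lang = vapply(od, `[[`, "", "lang"),
        datatype = vapply(od, `[[`, "", "datatype"))
    }
    stmts <- if (length(out)) dedupStatements(do.call(rbind, out)) else emptyStatements()
    return(list(type = "graph", statements = stmts))
  }
  ## SELECT
  vars <- if (identical(ast$vars, "*")) groupVars(ast$group) else ast$vars
  for (v in vars) if (!v %in% names(sol)) sol[[v]] <- rep(NA_character_, nrow(sol))
  sol <- sol[, vars, drop = FALSE]
  if (ast$distinct) sol <- sol[!duplicated(sol), , drop = FALSE]
  if (!is.null(ast$orderBy) && ast$orderBy %in% names(sol))
    sol <- sol[order(sol[[ast$orderBy]], decreasing = ast$orderDesc), , drop = FALSE]
  if (ast$offset > 0L) sol <- sol[-seq_len(min(ast$offset, nrow(sol))), , drop = FALSE]
  if (!is.na(ast$limit)) sol <- utils::head(sol, ast$limit)
  row.names(sol) <- NULL
  list(type = "select", vars = vars, solutions = sol)
}

## --- result serialization -------------------------------------------------

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

bindingFields <- function(enc) {
  t <- decTerm(enc)
  if (t$kind == "uri") return(list(type = "uri", value = t$value))
  out <- list(type = "literal", value = t$value)
  if (nzchar(t$lang)) out[["xml:lang"]] <- t$lang
  if (nzchar(t$datatype)) out$datatype <- t$datatype
  out
}

#' Serialize a SPARQL result
#'
#' SELECT and ASK results are rendered in the standard SPARQL results
#' formats: XML (\code{"xml"}), JSON (\code{"js"}) or CSV (\code{"csv"};
#' kind/lang/datatype columns are appended per variable so the table
#' round-trips without loss). Graph results (CONSTRUCT/DESCRIBE) are
#' rendered as RDF: Turtle for \code{"csv"}, RDF/XML otherwise.
#'
#' @param result Result object from \code{\link{sparqlQuery}}.
#' @param output Format token: "xml", "js" or "csv" ("rdf" also accepted
#'   for graph results).
#' @param prefixes Prefix map used by RDF serializations.
#' @return A single string.
#' @export
serializeSparqlResult <- function(result, output = "xml",
                                  prefixes = basePrefixes()) {
  if (!output %in% c("xml", "js", "csv", "rdf"))
    skbStop("seedkb_client_error", sprintf("unknown output format '%s'", output))
  if (result$type == "graph") {
    fmt <- if (output == "csv") "turtle" else "rdfxml"
    return(serializeRDF(result$statements, fmt, prefixes))
  }
  if (result$type == "ask") {
    return(switch(output,
      xml = paste0("<?xml version=\"1.0\"?>\n",
                   "<sparql xmlns=\"http://www.w3.org/2005/sparql-results#\">",
                   "<head/><boolean>", tolower(result$value), "</boolean></sparql>\n"),
      js = jsonlite::toJSON(list(head = stats::setNames(list(), character()),
                                 boolean = result$value), auto_unbox = TRUE),
      csv = paste0("boolean\n", tolower(result$value), "\n"),
      rdf = skbStop("seedkb_client_error", "ASK results have no RDF serialization")))
  }
  vars <- result$vars; sol <- result$solutions
  if (output == "xml") {
    head <- paste0("<head>", paste0("<variable name=\"", vars, "\"/>",
                                    collapse = ""), "</head>")
    rows <- vapply(seq_len(nrow(sol)), function(i) {
      bs <- vapply(vars, function(v) {
        enc <- sol[[v]][i]
        if (is.na(enc)) return("")
        f <- bindingFields(enc)
        inner <- if (f$type == "uri")
          paste0("<uri>", xmlEscape(f$value), "</uri>")
        else {
          attrs <- ""
          if (!is.null(f[["xml:lang"]])) attrs <- paste0(" xml:lang=\"", f[["xml:lang"]], "\"")
          if (!is.null(f$datatype)) attrs <- paste0(" datatype=\"", xmlEscape(f$datatype), "\"")
          paste0("<literal", attrs, ">", xmlEscape(f$value), "</literal>")
        }
        paste0("<binding name=\"", v, "\">", inner, "</binding>")
      }, "")
      paste0("<result>", paste(bs, collapse = ""), "</result>")
    }, "")
    return(paste0("<?xml version=\"1.0\"?>\n",
                  "<sparql xmlns=\"http://www.w3.org/2005/sparql-results#\">",
                  head, "<results>", paste(rows, collapse = ""),
                  "</results></sparql>\n"))
  }
  if (output == "js") {
    bindings <- lapply(seq_len(nrow(sol)), function(i) {
      b <- list()
      for (v in vars) {
        enc <- sol[[v]][i]
        if (!is.na(enc)) b[[v]] <- bindingFields(enc)
      }
      b
    })
    return(as.character(jsonlite::toJSON(
      list(head = list(vars = vars), results = list(bindings = bindings)),
      auto_unbox = TRUE)))
  }
  ## csv: one column per variable plus per-variable term metadata so the
  ## statement set can be reconstructed
  cols <- list()
  for (v in vars) {
    dec <- lapply(sol[[v]], function(e) if (is.na(e)) NULL else decTerm(e))
    cols[[v]] <- vapply(dec, function(d) if (is.null(d)) "" else d$value, "")
    cols[[paste0(v, "_kind")]] <-
      vapply(dec, function(d) if (is.null(d)) "" else d$kind, "")
    cols[[paste0(v, "_lang")]] <-
      vapply(dec, function(d) if (is.null(d)) "" else d$lang, "")
    cols[[paste0(v, "_datatype")]] <-
      vapply(dec, function(d) if (is.null(d)) "" else d$datatype, "")
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  tc <- textConnection("csvout", "w", local = TRUE)
  utils::write.csv(df, tc, row.names = FALSE)
  close(tc)
  paste0(paste(csvout, collapse = "\n"), "\n")
}
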