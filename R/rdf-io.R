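## RDF serialization and parsing: Turtle and RDF/XML.
##
## The dialect covered is the one setup graphs and serialized knowledge
## bases actually use: IRIs, prefixed names, plain/typed/lang literals and
## numeric shorthand. No blank nodes or collections — the seed model never
## produces them, and a parse error is preferable to silent acceptance.

TTL_ESCAPES <- c("\\" = "\\\\", "\"" = "\\\"", "\n" = "\\n",
                 "\r" = "\\r", "\t" = "\\t")

escapeTurtle <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescapeTurtle <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    res <- ""
    while (nchar(s)) {
      m <- regexpr("\\\\", s, fixed = FALSE)
      if (m == -1L) { res <- paste0(res, s); break }
      res <- paste0(res, substr(s, 1L, m - 1L))
      esc <- substr(s, m + 1L, m + 1L)
      res <- paste0(res, switch(esc, n = "\n", r = "\r", t = "\t",
                                "\"" = "\"", "\\" = "\\", esc))
      s <- substring(s, m + 2L)
    }
    out[[i]] <- res
  }
  out
}

ttlTerm <- function(value, kind, lang, datatype, prefixes) {
  if (kind == "uri") {
    c <- compactURI(value, prefixes)
    if (c != value) return(c)
    return(paste0("<", value, ">"))
  }
  lit <- paste0("\"", escapeTurtle(value), "\"")
  if (nzchar(lang)) return(paste0(lit, "@", lang))
  if (nzchar(datatype)) {
    dt <- compactURI(datatype, prefixes)
    if (dt == datatype) dt <- paste0("<", datatype, ">")
    return(paste0(lit, "^^", dt))
  }
  lit
}

#' Serialize statements to Turtle
#'
#' @param statements Statement data.frame (see \code{\link{makeStatements}}).
#' @param prefixes Named character vector used both for @prefix headers and
#'   CURIE compaction.
#' @return A single Turtle document string.
#' @export
serializeTurtle <- function(statements, prefixes = basePrefixes()) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  if (!nrow(statements)) return(paste(c(header, ""), collapse = "\n"))
  st <- statements[order(statements$subject, statements$predicate,
                         statements$object), , drop = FALSE]
  lines <- character()
  for (subj in unique(st$subject)) {
    rows <- st[st$subject == subj, , drop = FALSE]
    subjTok <- ttlTerm(subj, "uri", "", "", prefixes)
    po <- vapply(seq_len(nrow(rows)), function(i) {
      predTok <- if (rows$predicate[i] == rdfType()) "a"
                 else ttlTerm(rows$predicate[i], "uri", "", "", prefixes)
      paste(predTok, ttlTerm(rows$object[i], rows$objectKind[i],
                             rows$lang[i], rows$datatype[i], prefixes))
    }, "")
    lines <- c(lines, paste0(subjTok, " ",
                             paste(po, collapse = " ;\n    "), " ."))
  }
  paste(c(header, "", lines, ""), collapse = "\n")
}

## --- Turtle scanner -------------------------------------------------------

ttlTokenize <- function(text) {
  tokens <- list()
  pos <- 1L; n <- nchar(text); line <- 1L
  advance <- function(str) line <<- line + lengths(regmatches(str, gregexpr("\n", str, fixed = TRUE)))
  while (pos <= n) {
    rest <- substring(text, pos)
    ws <- regmatches(rest, regexpr("^([ \t\r\n]+|#[^\n]*)", rest))
    if (length(ws)) { advance(ws); pos <- pos + nchar(ws); next }
    matched <- NULL; type <- NULL
    pats <- c(iri = "^<[^<>\"{}|^`\\\\[:space:]]*>",
              string = "^\"([^\"\\\\]|\\\\.)*\"",
              dtype_sep = "^\\^\\^",
              directive = "^(@prefix|@base)\\b",
              lang = "^@[A-Za-z]+(-[A-Za-z0-9]+)*",
              sparql_directive = "^(PREFIX|BASE)\\b",
              boolean = "^(true|false)\\b",
              number = "^[+-]?[0-9]+(\\.[0-9]+)?",
              pname = "^([A-Za-z_][A-Za-z0-9_.-]*)?:[A-Za-z0-9_][A-Za-z0-9_.%-]*|^([A-Za-z_][A-Za-z0-9_.-]*)?:",
              kw_a = "^a\\b",
              punct = "^[.;,]")
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(pats[[ty]], rest, perl = TRUE))
      if (length(m)) { matched <- m; type <- ty; break }
    }
    if (is.null(matched))
      skbStop("seedkb_parse_error",
              sprintf("Turtle parse error at line %d near '%s'",
                      line, substr(rest, 1L, 30L)), line = line)
    tokens[[length(tokens) + 1L]] <- list(type = type, text = matched, line = line)
    advance(matched)
    pos <- pos + nchar(matched)
  }
  tokens
}

#' Parse a Turtle document
#'
#' @param text Turtle source text.
#' @return List with \code{statements} (data.frame) and \code{prefixes}.
#' @export
parseTurtle <- function(text) {
  toks <- ttlTokenize(stripBOM(text))
  prefixes <- character(); base <- ""
  out <- vector("list", 256L); nOut <- 0L
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[[i]] else NULL
  take <- function() {
    if (i > length(toks))
      skbStop("seedkb_parse_error", "Turtle parse error: unexpected end of input")
    t <- toks[[i]]; i <<- i + 1L; t
  }
  expect <- function(type) {
    t <- peek()
    if (is.null(t) || t$type != type)
      skbStop("seedkb_parse_error",
              sprintf("Turtle parse error at line %d: expected %s",
                      if (is.null(t)) -1L else t$line, type))
    take()
  }
  resolveTerm <- function(t) {
    if (t$type == "iri") {
      u <- substr(t$text, 2L, nchar(t$text) - 1L)
      if (!isAbsoluteURI(u) && nzchar(base)) u <- paste0(base, u)
      return(list(value = u, kind = "uri", lang = "", datatype = ""))
    }
    if (t$type == "pname") {
      pfx <- sub(":.*$", "", t$text)
      loc <- sub("^[^:]*:", "", t$text)
      if (!pfx %in% names(prefixes) && nzchar(pfx))
        skbStop("seedkb_parse_error",
                sprintf("undeclared prefix '%s' at line %d", pfx, t$line))
      ns <- if (nzchar(pfx)) prefixes[[pfx]] else prefixes[[""]] %||% SEED_NS
      return(list(value = paste0(ns, loc), kind = "uri", lang = "", datatype = ""))
    }
    if (t$type == "kw_a")
      return(list(value = rdfType(), kind = "uri", lang = "", datatype = ""))
    if (t$type == "string") {
      val <- unescapeTurtle(substr(t$text, 2L, nchar(t$text) - 1L))
      lang <- ""; dt <- ""
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "lang") {
        lang <- substring(take()$text, 2L)
      } else if (!is.null(nxt) && nxt$type == "dtype_sep") {
        take()
        dt <- resolveTerm(take())$value
      }
      return(list(value = val, kind = "literal", lang = lang, datatype = dt))
    }
    if (t$type == "number") {
      dt <- paste0(XSD_NS, if (grepl(".", t$text, fixed = TRUE)) "decimal" else "integer")
      return(list(value = t$text, kind = "literal", lang = "", datatype = dt))
    }
    if (t$type == "boolean")
      return(list(value = t$text, kind = "literal", lang = "",
                  datatype = paste0(XSD_NS, "boolean")))
    skbStop("seedkb_parse_error",
            sprintf("unexpected token '%s' at line %d", t$text, t$line))
  }
  emit <- function(s, p, o) {
    nOut <<- nOut + 1L
    if (nOut > length(out)) out[[2L * nOut]] <<- NULL
    out[[nOut]] <<- data.frame(subject = s$value, predicate = p$value,
                               object = o$value, objectKind = o$kind,
                               lang = o$lang, datatype = o$datatype,
                               graph = "", stringsAsFactors = FALSE)
  }
  while (!is.null(peek())) {
    t <- peek()
    if (t$type %in% c("directive", "sparql_directive")) {
      d <- take()
      isPrefix <- grepl("prefix", d$text, ignore.case = TRUE)
      if (isPrefix) {
        pn <- expect("pname")
        pfx <- sub(":.*$", "", pn$text)
        iri <- expect("iri")
        prefixes[[pfx]] <- substr(iri$text, 2L, nchar(iri$text) - 1L)
      } else {
        iri <- expect("iri")
        base <- substr(iri$text, 2L, nchar(iri$text) - 1L)
      }
      if (startsWith(d$text, "@")) expect("punct")
      next
    }
    subj <- resolveTerm(take())
    repeat {
      pred <- resolveTerm(take())
      repeat {
        obj <- resolveTerm(take())
        emit(subj, pred, obj)
        sep <- expect("punct")
        if (sep$text == ",") next
        if (sep$text == ";") {
          ## allow trailing ';' before '.'
          nxt <- peek()
          if (!is.null(nxt) && nxt$type == "punct" && nxt$text == ".") {
            take(); sep <- list(text = ".")
          }
          break
        }
        break
      }
      if (sep$text == ".") break
    }
  }
  statements <- if (nOut) do.call(rbind, out[seq_len(nOut)]) else emptyStatements()
  list(statements = dedupStatements(statements), prefixes = prefixes)
}

## --- RDF/XML --------------------------------------------------------------

## Assign printable prefixes to every namespace needed by the statements,
## reusing the supplied map and inventing ns1, ns2, ... for the rest.
collectNamespaces <- function(statements, prefixes) {
  splitNS <- function(u) sub("([/#])[^/#]*$", "\\1", u)
  used <- unique(c(RDF_NS, splitNS(statements$predicate),
                   splitNS(statements$subject[statements$objectKind == "uri"])))
  known <- unname(prefixes)
  extra <- setdiff(used, known)
  extra <- extra[isAbsoluteURI(extra)]
  if (length(extra)) {
    names(extra) <- paste0("ns", seq_along(extra))
    prefixes <- c(prefixes, extra)
  }
  prefixes
}

xmlQName <- function(uri, prefixes) {
  ord <- order(nchar(prefixes), decreasing = TRUE)
  for (i in ord) {
    ns <- prefixes[[i]]
    if (startsWith(uri, ns) && nchar(uri) > nchar(ns)) {
      loc <- substring(uri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_.%-]*$", loc))
        return(paste0(names(prefixes)[i], ":", loc))
    }
  }
  NULL
}

#' Serialize statements to RDF/XML
#'
#' @inheritParams serializeTurtle
#' @return RDF/XML document string.
#' @export
serializeRDFXML <- function(statements, prefixes = basePrefixes()) {
  prefixes <- collectNamespaces(statements, prefixes)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub("\"", "&quot;", x, fixed = TRUE)
  }
  decls <- sprintf("xmlns:%s=\"%s\"", names(prefixes), esc(unname(prefixes)))
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<rdf:RDF ", paste(decls, collapse = "\n         "), ">"))
  st <- statements[order(statements$subject, statements$predicate,
                         statements$object), , drop = FALSE]
  for (subj in unique(st$subject)) {
    rows <- st[st$subject == subj, , drop = FALSE]
    lines <- c(lines, sprintf("  <rdf:Description rdf:about=\"%s\">", esc(subj)))
    for (i in seq_len(nrow(rows))) {
      qn <- xmlQName(rows$predicate[i], prefixes)
      if (is.null(qn))
        skbStop("seedkb_parse_error",
                sprintf("predicate URI not expressible as XML QName: %s",
                        rows$predicate[i]))
      if (rows$objectKind[i] == "uri") {
        lines <- c(lines, sprintf("    <%s rdf:resource=\"%s\"/>",
                                  qn, esc(rows$object[i])))
      } else {
        attrs <- ""
        if (nzchar(rows$lang[i]))
          attrs <- sprintf(" xml:lang=\"%s\"", rows$lang[i])
        if (nzchar(rows$datatype[i]))
          attrs <- sprintf(" rdf:datatype=\"%s\"", esc(rows$datatype[i]))
        lines <- c(lines, sprintf("    <%s%s>%s</%s>",
                                  qn, attrs, esc(rows$object[i]), qn))
      }
    }
    lines <- c(lines, "  </rdf:Description>")
  }
  paste(c(lines, "</rdf:RDF>", ""), collapse = "\n")
}

#' Parse an RDF/XML document
#'
#' Handles the description-element dialect used by setup graphs: typed or
#' untyped node elements with \code{rdf:about}, property elements carrying
#' \code{rdf:resource}, nested node elements, text literals with optional
#' \code{rdf:datatype} / \code{xml:lang}.
#'
#' @param text RDF/XML source text.
#' @return List with \code{statements} and \code{prefixes}.
#' @export
parseRDFXML <- function(text) {
  doc <- tryCatch(xml2::read_xml(stripBOM(text)),
                  error = function(e)
                    skbStop("seedkb_parse_error",
                            paste("malformed RDF/XML:", conditionMessage(e))))
  nsmap <- xml2::xml_ns(doc)
  prefixes <- stats::setNames(as.character(nsmap), names(nsmap))
  prefixes <- prefixes[names(prefixes) != ""]
  expandName <- function(node) {
    nm <- xml2::xml_name(node, nsmap)  # "prefix:local" or bare local
    if (grepl(":", nm, fixed = TRUE)) {
      pfx <- sub(":.*$", "", nm)
      paste0(prefixes[[pfx]], sub("^[^:]*:", "", nm))
    } else nm
  }
  out <- list()
  emit <- function(s, p, o, kind, lang = "", dt = "")
    out[[length(out) + 1L]] <<- makeStatements(s, p, o, kind, lang, dt)
  rdfAttr <- function(node, what) {
    a <- xml2::xml_attr(node, what, ns = nsmap)
    if (is.na(a)) NULL else a
  }
  walkNode <- function(node) {
    subj <- rdfAttr(node, "rdf:about") %||% rdfAttr(node, "about")
    if (is.null(subj))
      skbStop("seedkb_parse_error",
              sprintf("node element <%s> lacks rdf:about (blank nodes unsupported)",
                      xml2::xml_name(node)))
    typeName <- expandName(node)
    if (typeName != paste0(RDF_NS, "Description"))
      emit(subj, rdfType(), typeName, "uri")
    for (prop in xml2::xml_children(node)) {
      pred <- expandName(prop)
      res <- rdfAttr(prop, "rdf:resource") %||% rdfAttr(prop, "resource")
      kids <- xml2::xml_children(prop)
      if (!is.null(res)) {
        emit(subj, pred, res, "uri")
      } else if (length(kids)) {
        for (kid in kids) {
          kidSubj <- walkNode(kid)
          emit(subj, pred, kidSubj, "uri")
        }
      } else {
        dt <- rdfAttr(prop, "rdf:datatype") %||% ""
        lang <- xml2::xml_attr(prop, "lang") %||% ""
        if (is.na(lang)) lang <- ""
        emit(subj, pred, xml2::xml_text(prop), "literal", lang, dt)
      }
    }
    subj
  }
  root <- xml2::xml_root(doc)
  if (expandName(root) == paste0(RDF_NS, "RDF")) {
    for (node in xml2::xml_children(root)) walkNode(node)
  } else {
    walkNode(root)
  }
  statements <- if (length(out)) do.call(rbind, out) else emptyStatements()
  list(statements = dedupStatements(statements), prefixes = prefixes)
}

#' Parse RDF in a named format
#' @param text Document text.
#' @param format "rdfxml" or "turtle"; "auto" sniffs the leading character.
#' @return List with \code{statements} and \code{prefixes}.
#' @export
parseRDF <- function(text, format = c("auto", "rdfxml", "turtle")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", text)) "rdfxml" else "turtle"
  switch(format, rdfxml = parseRDFXML(text), turtle = parseTurtle(text))
}

#' Serialize statements in a named format
#' @param statements Statement data.frame.
#' @param format "turtle" (default) or "rdfxml".
#' @param prefixes Prefix map for compaction.
#' @return Document text.
#' @export
serializeRDF <- function(statements, format = c("turtle", "rdfxml"),
                         prefixes = basePrefixes()) {
  format <- match.arg(format)
  switch(format, turtle = serializeTurtle(statements, prefixes),
         rdfxml = serializeRDFXML(statements, prefixes))
}
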