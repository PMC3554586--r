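mkSel <- function(key, q, props = "dc:identifier", isKey = FALSE)
  new("Selector", key = key, query = q, properties = props, isKey = isKey)

test_that("file URIs fetch the file's text content", {
  path <- writeTempCsv(c("id,symbol", "G1,BRCA2"))
  spec <- new("FetchSpec", uri = paste0("file://", path), kind = "csv")
  expect_equal(fetchSource(spec), "id,symbol\nG1,BRCA2")
})

test_that("endpoint templates substitute the item identifier", {
  r <- new("ResourceDef", key = "up", kind = "xml", method = "complete",
           endpoint = "http://www.uniprot.org/uniprot/#replace#.rdf",
           connectorHint = "xml", conceptKey = "UniProt",
           extendsKey = "UniProt", selectors = list(), order = 0L,
           extras = list())
  spec <- fetchSpec(r, "P51587")
  expect_equal(spec@uri, "http://www.uniprot.org/uniprot/P51587.rdf")
  ## a residual token is a validity violation
  expect_error(new("FetchSpec", uri = "http://x/#replace#", kind = "xml"))
})

test_that("an unreachable URI raises a fetch error carrying the URI", {
  spec <- new("FetchSpec", uri = "file:///nonexistent-seedkb-path", kind = "csv")
  err <- tryCatch(fetchSource(spec), error = function(e) e)
  expect_s3_class(err, "seedkb_fetch_error")
  expect_match(conditionMessage(err), "nonexistent-seedkb-path")
})

test_that("CSV selectors index 0-based columns, one record per data row", {
  rs <- selectCSV("id,symbol\nG1,BRCA2\nG2,TP53",
                  list(mkSel("sid", "0", isKey = TRUE)))
  expect_equal(recordCount(rs), 2L)
  expect_equal(rs@records[[1L]]$sid, "G1")
  expect_equal(rs@records[[2L]]$sid, "G2")
})

test_that("the CSV header row is excluded from the records", {
  content <- paste(c("h1,h2", paste0("r", 1:5, ",v")), collapse = "\n")
  rs <- selectCSV(content, list(mkSel("s", "0", isKey = TRUE)), header = TRUE)
  expect_equal(recordCount(rs), 5L)  # line count - 1
  rsNoHeader <- selectCSV(content, list(mkSel("s", "0", isKey = TRUE)),
                          header = FALSE)
  expect_equal(recordCount(rsNoHeader), 6L)
})

test_that("ragged CSV rows are skipped and reported", {
  content <- "a,b\nG1,BRCA2\nG2\nG3,TP53"
  rs <- selectCSV(content, list(mkSel("s0", "0", isKey = TRUE),
                                mkSel("s1", "1", props = "rdfs:label")))
  ## brute-force enumeration of violating rows
  rows <- strsplit(c("G1,BRCA2", "G2", "G3,TP53"), ",")
  violating <- sum(vapply(rows, function(r) length(r) < 2L, TRUE))
  expect_equal(nrow(rs@skips), violating)
  expect_equal(recordCount(rs) + nrow(rs@skips), 3L)
})

test_that("quoted CSV fields keep embedded separators and quotes", {
  rs <- selectCSV("h\n\"a,b\",\"say \"\"hi\"\"\"",
                  list(mkSel("s0", "0", isKey = TRUE),
                       mkSel("s1", "1", props = "rdfs:label")))
  expect_equal(rs@records[[1L]]$s0, "a,b")
  expect_equal(rs@records[[1L]]$s1, 'say "hi"')
})

protXML <- paste0(
  "<proteins>",
  "<entry><accession>P51587</accession><name>BRCA2</name>",
  "<dbReference id=\"1ycr\"/><dbReference id=\"2pcx\"/>",
  "<dbReference id=\"3abc\"/></entry>",
  "<entry><accession>P02461</accession><name>CO3A1</name></entry>",
  "</proteins>")

test_that("XML selectors yield one record per record-path node", {
  rs <- selectXML(protXML, list(mkSel("acc", "accession/text()",
                                      isKey = TRUE)),
                  recordPath = "//entry")
  ## independent count through a plain xml2 tree walk
  nEntries <- length(xml2::xml_find_all(xml2::read_xml(protXML), "//entry"))
  expect_equal(recordCount(rs), nEntries)
  expect_equal(rs@records[[1L]]$acc, "P51587")
  expect_equal(rs@records[[2L]]$acc, "P02461")
})

test_that("a selector matching nothing keeps the record with an empty list", {
  rs <- selectXML(protXML, list(mkSel("acc", "accession/text()", isKey = TRUE),
                                mkSel("none", "nosuch/text()",
                                      props = "dc:title")),
                  recordPath = "//entry")
  expect_equal(recordCount(rs), 2L)
  expect_length(rs@records[[1L]]$none, 0L)
})

test_that("multi-match selectors collect all values in document order", {
  rs <- selectXML(protXML, list(mkSel("acc", "accession/text()", isKey = TRUE),
                                mkSel("refs", "dbReference/@id",
                                      props = "dc:relation")),
                  recordPath = "//entry")
  ## manual node enumeration for the first entry
  doc <- xml2::read_xml(protXML)
  manual <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//entry[1]/dbReference"), "id")
  expect_equal(rs@records[[1L]]$refs, manual)
  expect_length(rs@records[[1L]]$refs, 3L)
})

test_that("malformed XML and invalid XPath raise classed errors", {
  expect_error(selectXML("<a><unclosed>", list(mkSel("s", "x", isKey = TRUE))),
               class = "seedkb_parse_error")
  err <- tryCatch(
    selectXML(protXML, list(mkSel("bad", "///[", isKey = TRUE)),
              recordPath = "//entry"),
    error = function(e) e)
  expect_s3_class(err, "seedkb_config_error")
  expect_match(conditionMessage(err), "bad")
})

test_that("SQL selectors take values by column name, NULL becoming empty", {
  tab <- data.frame(id = c("1", "2"), symbol = c("BRCA2", NA),
                    stringsAsFactors = FALSE)
  rs <- selectSQL(tab, list(mkSel("sid", "id", isKey = TRUE),
                            mkSel("sym", "symbol", props = "rdfs:label")))
  expect_equal(recordCount(rs), 2L)
  expect_equal(rs@records[[1L]]$sym, "BRCA2")
  expect_length(rs@records[[2L]]$sym, 0L)
  expect_error(selectSQL(tab, list(mkSel("x", "nosuch", isKey = TRUE))),
               class = "seedkb_config_error")
})

test_that("the embedded SQL bridge returns every inserted row", {
  db <- tempfile(fileext = ".db")
  n <- 100L
  sqlQuery(db, paste(c("CREATE TABLE genes (id TEXT, symbol TEXT);",
                       sprintf("INSERT INTO genes VALUES ('G%d', 'S%d');",
                               seq_len(n), seq_len(n))),
                     collapse = "\n"), mode = "script")
  tab <- sqlQuery(paste0("sqlite:///", db), "SELECT id, symbol FROM genes")
  expect_equal(ncol(tab), 2L)
  expect_equal(nrow(tab), n)
  rs <- selectSQL(tab, list(mkSel("sid", "id", isKey = TRUE)))
  expect_equal(recordCount(rs), n)
})

test_that("SPARQL selectors map solutions to records, unbound becoming empty", {
  kb <- KnowledgeBase()
  addStatements(kb, rbind(
    makeStatements("http://x/g1", dcTerm("identifier"), "G1"),
    makeStatements("http://x/g1", dcTerm("title"), "BRCA2"),
    makeStatements("http://x/g2", dcTerm("identifier"), "G2")))
  res <- sparqlQuery(kb, paste0(
    "PREFIX dc: <", seedkb:::DC_NS, ">\n",
    "SELECT ?g ?t WHERE { ?s dc:identifier ?g . ",
    "OPTIONAL { ?s dc:title ?t } }"))
  rs <- selectSPARQL(res, list(mkSel("gid", "g", isKey = TRUE),
                               mkSel("ttl", "t", props = "dc:title")))
  expect_equal(recordCount(rs), 2L)
  byId <- rs@records[order(vapply(rs@records, function(r) r$gid, ""))]
  expect_equal(byId[[1L]]$gid, "G1")
  expect_length(byId[[2L]]$ttl, 0L)
  expect_error(selectSPARQL(res, list(mkSel("x", "nosuch", isKey = TRUE))),
               class = "seedkb_config_error")
})

test_that("URI bindings keep their term kind through the record set", {
  kb <- KnowledgeBase()
  addStatements(kb, makeStatements("http://x/g1", seedTerm("isAssociatedTo"),
                                   "http://x/p1", "uri"))
  res <- sparqlQuery(kb, "SELECT ?s ?o WHERE { ?s ?p ?o }")
  rs <- selectSPARQL(res, list(mkSel("s", "s", isKey = TRUE),
                               mkSel("o", "o", props = "dc:relation")))
  expect_equal(rs@kinds[[1L]]$o, "uri")
  expect_equal(rs@records[[1L]]$o[1L], "http://x/p1")
})

test_that("the same logical data yields value-identical records from all four connectors", {
  genes <- data.frame(id = c("G1", "G2", "G3"),
                      symbol = c("BRCA2", "TP53", "CFTR"),
                      stringsAsFactors = FALSE)
  ## CSV
  csv <- paste(c("id,symbol", paste(genes$id, genes$symbol, sep = ",")),
               collapse = "\n")
  rsCsv <- selectCSV(csv, list(mkSel("k", "0", isKey = TRUE),
                               mkSel("v", "1", props = "rdfs:label")))
  ## XML
  xml <- paste0("<genes>",
                paste0("<gene><id>", genes$id, "</id><symbol>",
                       genes$symbol, "</symbol></gene>", collapse = ""),
                "</genes>")
  rsXml <- selectXML(xml, list(mkSel("k", "id/text()", isKey = TRUE),
                               mkSel("v", "symbol/text()",
                                     props = "rdfs:label")),
                     recordPath = "//gene")
  ## SQL
  db <- tempfile(fileext = ".db")
  sqlQuery(db, paste(c("CREATE TABLE g (id TEXT, symbol TEXT);",
                       sprintf("INSERT INTO g VALUES ('%s','%s');",
                               genes$id, genes$symbol)), collapse = "\n"),
           mode = "script")
  tab <- sqlQuery(db, "SELECT id, symbol FROM g ORDER BY id")
  rsSql <- selectSQL(tab, list(mkSel("k", "id", isKey = TRUE),
                               mkSel("v", "symbol", props = "rdfs:label")))
  ## SPARQL
  kb <- KnowledgeBase()
  for (i in seq_len(nrow(genes)))
    addStatements(kb, rbind(
      makeStatements(paste0("http://x/", genes$id[i]), dcTerm("identifier"),
                     genes$id[i]),
      makeStatements(paste0("http://x/", genes$id[i]), rdfsLabel(),
                     genes$symbol[i])))
  res <- sparqlQuery(kb, paste0(
    "PREFIX dc: <", seedkb:::DC_NS, ">\nPREFIX rdfs: <", seedkb:::RDFS_NS,
    ">\nSELECT ?k ?v WHERE { ?s dc:identifier ?k . ?s rdfs:label ?v } ",
    "ORDER BY ?k"))
  rsSparql <- selectSPARQL(res, list(mkSel("k", "k", isKey = TRUE),
                                     mkSel("v", "v", props = "rdfs:label")))
  canon <- function(rs) {
    vals <- lapply(rs@records, function(r) c(r$k, r$v))
    vals[order(vapply(vals, `[[`, "", 1L))]
  }
  ref <- canon(rsCsv)
  expect_equal(canon(rsXml), ref)
  expect_equal(canon(rsSql), ref)
  expect_equal(canon(rsSparql), ref)
})

test_that("record counts are conserved: records + skips = source units", {
  content <- paste(c("h", "a,1", "b", "c,3", "d"), collapse = "\n")
  rs <- selectCSV(content, list(mkSel("s0", "0", isKey = TRUE),
                                mkSel("s1", "1", props = "dc:title")))
  expect_equal(recordCount(rs) + nrow(rs@skips), 4L)
})

test_that("querying a registered endpoint equals querying its store directly", {
  kb <- KnowledgeBase()
  addStatements(kb, makeStatements(sprintf("http://x/g%d", 1:3),
                                   dcTerm("identifier"),
                                   sprintf("G%d", 1:3)))
  registry <- EndpointRegistry()
  registerEndpoint(registry, "endpoint:local", kb)
  q <- paste0("PREFIX dc: <", seedkb:::DC_NS,
              ">\nSELECT ?g WHERE { ?s dc:identifier ?g } ORDER BY ?g")
  direct <- sparqlQuery(kb, q)
  r <- new("ResourceDef", key = "r", kind = "sparql", method = "cache",
           endpoint = "endpoint:local", connectorHint = "sparql",
           conceptKey = "C", extendsKey = NA_character_,
           selectors = list(mkSel("g", "g", isKey = TRUE)), order = 0L,
           extras = list("seed:queryText" = q))
  rs <- selectRecords(r, registry = registry)
  rsDirect <- selectSPARQL(direct, r@selectors)
  expect_equal(rs@records, rsDirect@records)
})
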