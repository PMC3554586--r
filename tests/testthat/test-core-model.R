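test_that("the simple gene-list setup parses to 1 resource with 2 CSV selectors", {
  m <- geneListModel("/tmp/genes.csv")
  text <- serializeModel(m, "rdfxml")
  parsed <- parseSetup(text, m@config)
  expect_length(parsed@resources, 1L)
  res <- parsed@resources[["HGNC"]]
  expect_equal(res@kind, "csv")
  expect_length(res@selectors, 2L)
  ## three configuration individuals: the resource plus two CSV selectors
  st <- parseRDF(text, "rdfxml")$statements
  types <- st[st$predicate == rdfType(), ]
  configIndividuals <- types$subject[types$object %in%
    c(seedTerm("Resource"), seedTerm("CSV"))]
  expect_length(unique(configIndividuals), 3L)
})

test_that("an empty setup document yields an empty model without errors", {
  empty <- paste0("<?xml version=\"1.0\"?><rdf:RDF xmlns:rdf=\"",
                  seedkb:::RDF_NS, "\"/>")
  m <- parseSetup(empty, new("SeedConfig", name = "empty"))
  expect_length(m@entities, 0L)
  expect_length(m@concepts, 0L)
  expect_length(m@resources, 0L)
  expect_equal(nrow(validateModel(m)), 0L)
})

test_that("a concept lacking its entity link is reported by name", {
  ttl <- paste0(
    "@prefix seed: <", seedkb:::SEED_NS, "> .\n",
    "@prefix rdfs: <", seedkb:::RDFS_NS, "> .\n",
    "@prefix kb: <http://localhost/seed/> .\n",
    "kb:concept_Orphan a seed:Concept ; rdfs:label \"Orphan\" .\n")
  expect_warning(
    m <- parseSetup(ttl, new("SeedConfig", name = "x",
                             baseNamespace = "http://localhost/seed/")),
    class = "seedkb_validation_warning")
  issues <- validateModel(m)
  expect_true(any(issues$rule == "concept-entity" &
                  issues$subject == "Orphan"))
})

test_that("an individual typed by an unknown vocabulary class is an error", {
  ttl <- paste0(
    "@prefix seed: <", seedkb:::SEED_NS, "> .\n",
    "<http://localhost/seed/x> a seed:Gadget .\n")
  expect_error(parseSetup(ttl, new("SeedConfig", name = "x")),
               regexp = "http://localhost/seed/x",
               class = "seedkb_validation_error")
})

test_that("a well-formed proteomics model validates cleanly", {
  expect_equal(nrow(validateModel(proteomicsModel())), 0L)
})

test_that("method/extends and key-selector cardinality violations are caught", {
  m <- proteomicsModel()
  ## complete without extends
  m2 <- m
  m2@resources$UniProt@method <- "complete"
  issues <- validateModel(m2)
  expect_true(any(issues$rule == "resource-extends"))
  ## two key selectors
  m3 <- m
  m3@resources$UniProt@selectors[[2L]]@isKey <- TRUE
  issues <- validateModel(m3)
  expect_true(any(issues$rule == "selector-key-cardinality"))
  ## CSV selector query must be a non-negative integer
  m4 <- m
  m4@resources$UniProt@selectors[[1L]]@query <- "id"
  issues <- validateModel(m4)
  expect_true(any(issues$rule == "csv-selector-query"))
})

test_that("parse/serialize is the identity on the proteomics and gene-list models", {
  for (m in list(proteomicsModel(), geneListModel("/tmp/g.csv"))) {
    for (fmt in c("turtle", "rdfxml")) {
      back <- parseSetup(serializeModel(m, fmt), m@config, format = fmt)
      expect_true(sameModel(m, back))
    }
  }
})

test_that("parse/serialize round-trips randomly generated small models", {
  set.seed(42)
  randModel <- function() {
    nc <- sample(1:3, 1)
    concepts <- paste0("C", seq_len(nc))
    config <- new("SeedConfig", name = "rand",
                  baseNamespace = "http://localhost/seed/",
                  prefixes = c(kb = "http://localhost/seed/"))
    ents <- list(E1 = new("EntityDef", key = "E1", label = "E1",
                          conceptKeys = concepts))
    cons <- list(); ress <- list()
    for (ck in concepts) {
      kind <- sample(c("csv", "xml", "sql", "sparql"), 1)
      q <- switch(kind, csv = as.character(sample(0:5, 1)),
                  xml = ".//id/text()", sql = "idcol", sparql = "v")
      sels <- list(new("Selector", key = paste0("sel_", ck, "_key"),
                       query = q, properties = "dc:identifier",
                       isKey = TRUE))
      if (runif(1) < 0.5)
        sels <- c(sels, list(new("Selector",
                                 key = paste0("sel_", ck, "_extra"),
                                 query = switch(kind, csv = "1", xml = ".//x",
                                                sql = "c2", sparql = "w"),
                                 properties = c("rdfs:label", "dc:title"))))
      ress[[ck]] <- new("ResourceDef", key = ck, kind = kind,
                        method = "cache", endpoint = "file:///dev/null",
                        connectorHint = kind, conceptKey = ck,
                        extendsKey = NA_character_, selectors = sels,
                        order = sample(0:9, 1), extras = list())
      cons[[ck]] <- new("ConceptDef", key = ck, entityKey = "E1",
                        label = paste("Concept", ck), resourceRefs = ck,
                        bridgeRefs = character())
    }
    new("SeedModel", config = config, entities = ents, concepts = cons,
        resources = ress, bridges = list())
  }
  for (i in 1:8) {
    m <- randModel()
    fmt <- if (i %% 2 == 0) "turtle" else "rdfxml"
    expect_true(sameModel(m, parseSetup(serializeModel(m, fmt), m@config,
                                        format = fmt)))
  }
})

test_that("unknown extra predicates on a resource are preserved verbatim", {
  m <- proteomicsModel()
  m@resources$UniProt@extras <- list("seed:recordPath" = "//entry",
                                     "dc:rights" = "open")
  back <- parseSetup(serializeModel(m, "turtle"), m@config, format = "turtle")
  ex <- back@resources$UniProt@extras
  expect_equal(unlist(ex[["seed:recordPath"]]), "//entry",
               ignore_attr = TRUE)
  expect_equal(unlist(ex[["dc:rights"]]), "open", ignore_attr = TRUE)
})

test_that("a resource that completes a concept runs after its providers", {
  m <- proteomicsModel()
  m@resources$Enrich <- new("ResourceDef", key = "Enrich", kind = "csv",
    method = "complete", endpoint = "file:///dev/null",
    connectorHint = "csv", conceptKey = "UniProt", extendsKey = "UniProt",
    selectors = list(new("Selector", key = "sel_e", query = "0",
                         properties = "dc:identifier", isKey = TRUE)),
    order = 0L, extras = list())
  m@concepts$UniProt@resourceRefs <- c("UniProt", "Enrich")
  ord <- buildDependencyOrder(m)
  expect_true(match("UniProt", ord) < match("Enrich", ord))
})

test_that("all-cache models order by (order, key) ascending", {
  m <- proteomicsModel()
  m@resources$UniProt@order <- 5L
  m@resources$OMIM@order <- 1L
  expect_equal(buildDependencyOrder(m), c("OMIM", "UniProt"))
  m@resources$OMIM@order <- 5L
  expect_equal(buildDependencyOrder(m), c("OMIM", "UniProt"))  # key tie-break
})

test_that("dependency cycles are detected and their members listed", {
  m <- proteomicsModel()
  m@resources$UniProt@method <- "complete"
  m@resources$UniProt@extendsKey <- "OMIM"
  m@resources$OMIM@method <- "complete"
  m@resources$OMIM@extendsKey <- "UniProt"
  err <- tryCatch(buildDependencyOrder(m), error = function(e) e)
  expect_s3_class(err, "seedkb_cycle_error")
  expect_match(conditionMessage(err), "OMIM")
  expect_match(conditionMessage(err), "UniProt")
})

test_that("the computed order is always among the brute-force valid orders", {
  set.seed(7)
  mkSel <- function(k) list(new("Selector", key = paste0("s_", k),
                                query = "0", properties = "dc:identifier",
                                isKey = TRUE))
  for (trial in 1:6) {
    n <- sample(3:6, 1)
    keys <- paste0("R", seq_len(n))
    config <- new("SeedConfig", name = "t",
                  baseNamespace = "http://localhost/seed/")
    cons <- list(); ress <- list()
    for (i in seq_len(n)) {
      k <- keys[[i]]
      ## resource i may extend the concept of an earlier resource (keeps
      ## the graph acyclic by construction)
      ext <- if (i > 1 && runif(1) < 0.6) keys[[sample(i - 1L, 1)]]
             else NA_character_
      ress[[k]] <- new("ResourceDef", key = k, kind = "csv",
        method = if (is.na(ext)) "cache" else "complete",
        endpoint = "file:///dev/null", connectorHint = "csv",
        conceptKey = k, extendsKey = ext, selectors = mkSel(k),
        order = sample(0:3, 1), extras = list())
      cons[[k]] <- new("ConceptDef", key = k, entityKey = "E",
                       label = k, resourceRefs = k, bridgeRefs = character())
    }
    m <- new("SeedModel", config = config,
             entities = list(E = new("EntityDef", key = "E", label = "E",
                                     conceptKeys = keys)),
             concepts = cons, resources = ress, bridges = list())
    ord <- buildDependencyOrder(m)
    after <- lapply(ress, function(r)
      if (is.na(r@extendsKey)) character() else r@extendsKey)
    valid <- allTopoOrders(keys, after)
    expect_true(any(vapply(valid, identical, TRUE, y = ord)))
  }
})

test_that("config.js parses and round-trips its fields", {
  js <- '{"name":"demo","version":"2.1","description":"d","environment":"prod",
          "namespace":"http://demo.local/kb/",
          "prefixes":{"kb":"http://demo.local/kb/"},
          "ontologies":["http://demo.local/onto.owl"]}'
  cfg <- parseSeedConfig(js)
  expect_equal(cfg@name, "demo")
  expect_equal(cfg@baseNamespace, "http://demo.local/kb/")
  expect_equal(unname(cfg@prefixes["kb"]), "http://demo.local/kb/")
  back <- parseSeedConfig(serializeSeedConfig(cfg))
  expect_equal(back@name, cfg@name)
  expect_equal(back@prefixes, cfg@prefixes)
  expect_equal(back@ontologyImports, cfg@ontologyImports)
})
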