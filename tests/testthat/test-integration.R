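NS <- "http://localhost/seed/"

test_that("item URIs follow the concept_identifier minting rule", {
  expect_equal(mintItemUri("UniProt", "P51587", NS),
               paste0(NS, "uniprot_P51587"))
  expect_equal(mintItemUri("OMIM", "114480", NS),
               paste0(NS, "omim_114480"))
  ## URI-reserved characters in the identifier are percent-encoded
  expect_equal(mintItemUri("HGNC", "HGNC:1101", NS),
               paste0(NS, "hgnc_HGNC%3A1101"))
  expect_error(mintItemUri("X", "", NS), class = "seedkb_build_error")
})

test_that("minting is injective up to the collision check", {
  expect_silent(seedkb:::checkMintCollisions("HGNC", c("A:1", "A:2"), NS))
  err <- tryCatch(seedkb:::checkMintCollisions("HGNC", c("A:1", "A%3A1"), NS),
                  error = function(e) e)
  expect_s3_class(err, "seedkb_build_error")
  expect_match(conditionMessage(err), "A:1")
  expect_match(conditionMessage(err), "A%3A1")
})

fig3Resource <- function() {
  new("ResourceDef", key = "HGNC", kind = "csv", method = "cache",
      endpoint = "", connectorHint = "csv", conceptKey = "HGNC",
      extendsKey = NA_character_,
      selectors = list(
        new("Selector", key = "csv_HGNC_id", query = "0",
            properties = c("dc:source", "dc:identifier"), isKey = TRUE)),
      order = 0L, extras = list())
}

test_that("one selector with two properties yields two pairs sharing one value", {
  rs <- selectCSV("h\nBRCA2", fig3Resource()@selectors)
  maps <- makeItemMaps(rs, fig3Resource())
  expect_length(maps, 1L)
  props <- maps[[1L]]@properties
  expect_equal(nrow(props), 2L)
  expect_setequal(props$predicate, c("dc:source", "dc:identifier"))
  expect_equal(unique(props$value), "BRCA2")
})

test_that("records with an empty key are skipped, not mapped", {
  rs <- seedkb:::newRecordSet(list(list(csv_HGNC_id = character())))
  maps <- makeItemMaps(rs, fig3Resource())
  expect_length(maps, 0L)
  expect_equal(attr(maps, "skips"), 1L)
})

test_that("multi-value selectors cross their values with their properties", {
  r <- fig3Resource()
  r@selectors <- list(
    new("Selector", key = "a", query = "0", properties = c("p:p", "p:q"),
        isKey = TRUE))
  rs <- seedkb:::newRecordSet(list(list(a = c("v1", "v2"))))
  maps <- makeItemMaps(rs, r)
  expect_equal(nrow(maps[[1L]]@properties), 4L)  # 2 values x 2 properties
})

test_that("triplification emits the worked-example statement pair", {
  m <- geneListModel("unused")
  kb <- KnowledgeBase(modelPrefixes(m))
  item <- new("ItemMap", identifier = "BRCA2", conceptKey = "HGNC",
              properties = data.frame(
                predicate = c("dc:source", "dc:identifier"),
                value = "BRCA2", kind = "literal",
                stringsAsFactors = FALSE))
  triplify(item, m, kb)
  subj <- mintItemUri("HGNC", "BRCA2", m@config@baseNamespace)
  propSt <- kbStatements(kb)
  propSt <- propSt[propSt$predicate %in% c(dcTerm("source"),
                                           dcTerm("identifier")), ]
  expect_equal(nrow(propSt), 2L)
  expect_equal(unique(propSt$subject), subj)   # same subject
  expect_equal(unique(propSt$object), "BRCA2") # same object
})

test_that("an empty property map produces structural statements only", {
  m <- geneListModel("unused")
  kb <- KnowledgeBase()
  item <- new("ItemMap", identifier = "X1", conceptKey = "HGNC",
              properties = data.frame(predicate = character(),
                                      value = character(),
                                      kind = character(),
                                      stringsAsFactors = FALSE))
  n <- triplify(item, m, kb)
  expect_equal(n, 4L)  # type, hasConcept, mirrored isConceptOf, label
  expect_equal(kbSize(kb), 4L)
})

test_that("re-triplifying an identical item adds zero statements", {
  m <- geneListModel("unused")
  kb <- KnowledgeBase()
  item <- new("ItemMap", identifier = "BRCA2", conceptKey = "HGNC",
              properties = data.frame(predicate = "dc:identifier",
                                      value = "BRCA2", kind = "literal",
                                      stringsAsFactors = FALSE))
  first <- triplify(item, m, kb)
  expect_gt(first, 0L)
  expect_equal(triplify(item, m, kb), 0L)
})

test_that("cache creates one item per distinct key, merging duplicates", {
  csv <- writeTempCsv(c("id,symbol", "G1,BRCA2", "G2,TP53", "G3,CFTR"))
  m <- geneListModel(csv)
  rep <- buildSeed(m)
  frag <- rep@resources[rep@resources$resource == "HGNC", ]
  expect_equal(frag$items, 3L)
  ## duplicate ids across rows merge into one item
  csv2 <- writeTempCsv(c("id,symbol", "G1,BRCA2", "G1,BRCA2B"))
  m2 <- geneListModel(csv2)
  rep2 <- buildSeed(m2)
  frag2 <- rep2@resources[1, ]
  expect_equal(frag2$items, 1L)
  kb2 <- attr(rep2, "kb")
  labels <- matchTriples(kb2, subject = mintItemUri("HGNC", "G1", NS),
                         predicate = rdfsLabel())
  expect_setequal(labels$object, c("BRCA2", "BRCA2B"))
})

test_that("an empty source builds zero items without errors", {
  csv <- writeTempCsv("id,symbol")
  rep <- buildSeed(geneListModel(csv))
  frag <- rep@resources[1, ]
  expect_equal(frag$items, 0L)
  expect_false(frag$failed)
})

test_that("a failing resource is isolated; the build continues", {
  csv <- writeTempCsv(c("id,symbol", "G1,BRCA2"))
  m <- geneListModel(csv)
  bad <- m@resources$HGNC
  bad@key <- "Broken"
  bad@endpoint <- "file:///definitely/missing.csv"
  bad@order <- 99L
  m@resources$Broken <- bad
  m@concepts$HGNC@resourceRefs <- c("HGNC", "Broken")
  rep <- buildSeed(m)
  df <- rep@resources
  expect_true(df$failed[df$resource == "Broken"])
  expect_false(df$failed[df$resource == "HGNC"])
  expect_equal(df$items[df$resource == "HGNC"], 1L)
  expect_true(buildFailed(rep))
})

completeFixture <- function(perItem = TRUE) {
  csv <- writeTempCsv(c("id,symbol", "G1,BRCA2", "G2,TP53"))
  m <- geneListModel(csv)
  if (perItem) {
    dir <- tempfile("xmlsrc-"); dir.create(dir)
    for (g in c("G1", "G2"))
      writeLines(sprintf("<gene><id>%s</id><desc>about %s</desc></gene>",
                         g, g), file.path(dir, paste0(g, ".xml")))
    endpoint <- paste0("file://", dir, "/#replace#.xml")
    sels <- list(new("Selector", key = "xml_id", query = "id/text()",
                     properties = "dc:identifier", isKey = TRUE),
                 new("Selector", key = "xml_desc", query = "desc/text()",
                     properties = "dc:description"))
    extras <- list("seed:recordPath" = "/*")
    kind <- "xml"
  } else {
    csv2 <- writeTempCsv(c("id,desc", "G1,about G1", "G2,about G2"))
    endpoint <- paste0("file://", csv2)
    sels <- list(new("Selector", key = "c_id", query = "0",
                     properties = "dc:identifier", isKey = TRUE),
                 new("Selector", key = "c_desc", query = "1",
                     properties = "dc:description"))
    extras <- list()
    kind <- "csv"
  }
  m@resources$Detail <- new("ResourceDef", key = "Detail", kind = kind,
    method = "complete", endpoint = endpoint, connectorHint = kind,
    conceptKey = "HGNC", extendsKey = "HGNC", selectors = sels,
    order = 10L, extras = extras)
  m@concepts$HGNC@resourceRefs <- c("HGNC", "Detail")
  m
}

test_that("complete appends to existing items and never creates new ones", {
  for (perItem in c(TRUE, FALSE)) {
    m <- completeFixture(perItem)
    rep <- buildSeed(m)
    kb <- attr(rep, "kb")
    df <- rep@resources
    nItems <- function() nrow(seedkb:::itemsOfConcept(kb, m, "HGNC"))
    expect_equal(df$items[df$resource == "Detail"], 0L)
    expect_equal(nItems(), 2L)
    ## exactly one appended description per item (per-item count oracle)
    expect_equal(df$statements[df$resource == "Detail"], 2L)
    for (g in c("G1", "G2")) {
      desc <- matchTriples(kb, subject = mintItemUri("HGNC", g, NS),
                           predicate = dcTerm("description"))
      expect_equal(desc$object, paste("about", g))
    }
  }
})

test_that("complete over an empty extended concept fetches nothing", {
  m <- completeFixture(TRUE)
  m@resources$HGNC@endpoint <- paste0("file://", writeTempCsv("id,symbol"))
  rep <- buildSeed(m)
  df <- rep@resources
  expect_equal(df$records[df$resource == "Detail"], 0L)
  expect_equal(df$statements[df$resource == "Detail"], 0L)
  expect_false(df$failed[df$resource == "Detail"])
})

mapFixture <- function(mapRows) {
  csvG <- writeTempCsv(c("id,symbol", "G1,BRCA2", "G2,TP53"))
  csvP <- writeTempCsv(c("acc,name", "P1,protA", "P2,protB", "P3,protC"))
  mapCsv <- writeTempCsv(c("acc,gene", mapRows))
  config <- new("SeedConfig", name = "mapfix", baseNamespace = NS,
                prefixes = c(kb = NS))
  sel <- function(key, q, props, isKey = FALSE)
    new("Selector", key = key, query = q, properties = props, isKey = isKey)
  res <- function(key, concept, endpoint, sels, method = "cache",
                  extends = NA_character_, order = 0L)
    new("ResourceDef", key = key, kind = "csv", method = method,
        endpoint = paste0("file://", endpoint), connectorHint = "csv",
        conceptKey = concept, extendsKey = extends, selectors = sels,
        order = as.integer(order), extras = list())
  new("SeedModel", config = config,
    entities = list(E = new("EntityDef", key = "E", label = "E",
                            conceptKeys = c("HGNC", "UniProt"))),
    concepts = list(
      HGNC = new("ConceptDef", key = "HGNC", entityKey = "E",
                 label = "HGNC", resourceRefs = "Genes",
                 bridgeRefs = character()),
      UniProt = new("ConceptDef", key = "UniProt", entityKey = "E",
                    label = "UniProt",
                    resourceRefs = c("Proteins", "Map"),
                    bridgeRefs = character())),
    resources = list(
      Genes = res("Genes", "HGNC", csvG,
                  list(sel("g_id", "0", "dc:identifier", TRUE)), order = 1L),
      Proteins = res("Proteins", "UniProt", csvP,
                     list(sel("p_id", "0", "dc:identifier", TRUE)),
                     order = 2L),
      Map = res("Map", "UniProt", mapCsv,
                list(sel("m_acc", "0", "dc:identifier", TRUE),
                     sel("m_gene", "1", "seed:isAssociatedTo")),
                method = "map", extends = "HGNC", order = 3L)),
    bridges = list())
}

test_that("map links existing items in both directions", {
  m <- mapFixture(c("P1,G1", "P2,G1", "P3,G2"))
  rep <- buildSeed(m)
  kb <- attr(rep, "kb")
  df <- rep@resources
  expect_equal(df$links[df$resource == "Map"], 3L)
  expect_equal(df$items[df$resource == "Map"], 0L)
  fwd <- matchTriples(kb, subject = mintItemUri("UniProt", "P1", NS),
                      predicate = seedTerm("isAssociatedTo"))
  expect_equal(fwd$object, mintItemUri("HGNC", "G1", NS))
  back <- matchTriples(kb, subject = mintItemUri("HGNC", "G1", NS),
                       predicate = seedTerm("isAssociatedTo"))
  expect_setequal(back$object, c(mintItemUri("UniProt", "P1", NS),
                                 mintItemUri("UniProt", "P2", NS)))
})

test_that("map skips pairs whose target item is missing", {
  m <- mapFixture(c("P1,G1", "P2,G9", "P3,G2"))  # G9 does not exist
  rep <- buildSeed(m)
  df <- rep@resources
  expect_equal(df$links[df$resource == "Map"], 2L)
  expect_equal(df$skips[df$resource == "Map"], 1L)
})

test_that("an empty mapping list creates zero links", {
  m <- mapFixture(character())
  rep <- buildSeed(m)
  expect_equal(rep@resources$links[rep@resources$resource == "Map"], 0L)
})

test_that("a model with zero resources yields only structural triples", {
  m <- proteomicsModel()
  m@resources <- list()
  m@concepts$UniProt@resourceRefs <- character()
  m@concepts$OMIM@resourceRefs <- character()
  rep <- buildSeed(m)
  kb <- attr(rep, "kb")
  expect_equal(nrow(rep@resources), 0L)
  st <- kbStatements(kb)
  expect_true(all(startsWith(st$subject, NS)))
  types <- st$object[st$predicate == rdfType()]
  expect_setequal(types, seedTerm(c("Seed", "Entity", "Concept")))
})

test_that("report totals are the sum of the per-resource fragments", {
  spec <- fixtureSpec(randomSeed = 5, nDiseases = 3L,
                      outputDir = tempfile())
  b <- generateFixtureSeed(spec)
  before <- KnowledgeBase(modelPrefixes(b$model))
  addStatements(before, seedkb:::seedStructureStatements(b$model))
  structural <- kbSize(before)
  rep <- buildSeed(b$model, registry = b$registry)
  kb <- attr(rep, "kb")
  expect_equal(kbSize(kb), structural + sum(rep@resources$statements))
})

test_that("statement counts obey the cross-product law (brute-force check)", {
  set.seed(11)
  for (trial in 1:3) {
    n <- sample(c(20L, 60L, 100L), 1L)
    ids <- sprintf("ID%03d", sample(150L, n, replace = TRUE))
    rows <- lapply(seq_len(n), function(i)
      c(ids[[i]], sprintf("sym%d", i %% 7L), sprintf("x%d", i %% 3L)))
    csv <- writeTempCsv(c("id,sym,x",
                          vapply(rows, paste, "", collapse = ",")))
    m <- geneListModel(csv)
    m@resources$HGNC@selectors <- list(
      new("Selector", key = "s0", query = "0",
          properties = c("dc:source", "dc:identifier"), isKey = TRUE),
      new("Selector", key = "s1", query = "1", properties = "dc:title"),
      new("Selector", key = "s2", query = "2",
          properties = c("dc:subject", "dc:relation")))
    rep <- buildSeed(m)
    got <- rep@resources$statements[1L]
    want <- bruteCacheCount(rows, m@resources$HGNC@selectors, "HGNC",
                            "HGNC", NS)
    expect_equal(got, want)
  }
})

test_that("building twice from identical inputs is idempotent", {
  spec <- fixtureSpec(randomSeed = 9, nDiseases = 3L,
                      outputDir = tempfile())
  b <- generateFixtureSeed(spec)
  rep1 <- buildSeed(b$model, registry = b$registry)
  kb <- attr(rep1, "kb")
  size1 <- kbSize(kb)
  rep2 <- buildSeed(b$model, kb = kb, registry = b$registry)
  expect_equal(kbSize(kb), size1)
  expect_equal(sum(rep2@resources$statements), 0L)
  ## and a fresh single build is graph-equal to the double build
  fresh <- attr(buildSeed(b$model, registry = b$registry), "kb")
  expect_true(sameGraph(kb, fresh))
})

test_that("complete never changes the number of Item individuals", {
  m <- completeFixture(FALSE)
  rep <- buildSeed(m)
  kb <- attr(rep, "kb")
  nItems <- length(unique(matchTriples(kb, predicate = rdfType(),
                                       object = seedTerm("Item"))$subject))
  expect_equal(nItems, 2L)
})

test_that("every built item passes the concept-consistency audit", {
  spec <- fixtureSpec(randomSeed = 2, nDiseases = 2L,
                      outputDir = tempfile())
  b <- generateFixtureSeed(spec)
  rep <- buildSeed(b$model, registry = b$registry)
  expect_equal(nrow(auditItems(attr(rep, "kb"))), 0L)
  expectNoSkips(rep)
})

test_that("building an invalid model is refused with the violation attached", {
  m <- proteomicsModel()
  m@resources$UniProt@method <- "complete"   # no extends -> invalid
  err <- tryCatch(buildSeed(m), error = function(e) e)
  expect_s3_class(err, "seedkb_validation_error")
})
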