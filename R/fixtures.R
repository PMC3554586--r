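## Deterministic offline fixtures emulating the rare-disease integration
## scenario: disease records fan out to genes, proteins and
## cross-references, published as CSV files, XML documents, an embedded
## SQLite database and an auxiliary in-process SPARQL endpoint. The same
## FixtureSpec always yields byte-identical files, and a closed-form
## manifest predicts every item and statement count the engine must
## produce.

DEFAULT_CONCEPTS <- c("OMIM", "HGNC", "UniProt", "PDB", "PROSITE",
                      "InterPro", "PharmGKB", "Entrez", "PubMed", "MeSH",
                      "Orphanet")

XREF_CONCEPTS <- c("PDB", "PROSITE", "InterPro", "PharmGKB")

#' Construct a fixture specification
#'
#' @param randomSeed Integer seed; drives every draw.
#' @param nDiseases Number of disease records.
#' @param genesPerDisease,proteinsPerGene,xrefsPerProtein Branching-factor
#'   ranges (length-2 min/max).
#' @param conceptList Concepts to include; the default covers eleven data
#'   types across all four connector kinds.
#' @param outputDir Directory for generated files.
#' @return A \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(randomSeed = 1L, nDiseases = 6L,
                        genesPerDisease = c(1L, 3L),
                        proteinsPerGene = c(1L, 2L),
                        xrefsPerProtein = c(1L, 3L),
                        conceptList = DEFAULT_CONCEPTS,
                        outputDir = tempfile("seedkb-fixture-")) {
  new("FixtureSpec", randomSeed = as.integer(randomSeed),
      nDiseases = as.integer(nDiseases),
      genesPerDisease = as.integer(rep_len(genesPerDisease, 2L)),
      proteinsPerGene = as.integer(rep_len(proteinsPerGene, 2L)),
      xrefsPerProtein = as.integer(rep_len(xrefsPerProtein, 2L)),
      conceptList = conceptList, outputDir = outputDir)
}

drawCounts <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

## Identifier factories mimic real shapes (OMIM 6-digit, UniProt
## [A-Z][0-9]{5}, PDB 4-character, HGNC/Orphanet with a colon) so the URI
## sanitization path is exercised; every value is synthetic.
fixtureIds <- list(
  omim     = function(n) as.character(sample(100000:699999, n)),
  mesh     = function(n) sprintf("D%06d", sample(1:999999, n)),
  orphanet = function(n) paste0("ORPHA:", sample(100:99999, n)),
  hgnc     = function(n) paste0("HGNC:", sample(1:49999, n)),
  symbol   = function(n) paste0(
    vapply(seq_len(n), function(i)
      paste(sample(LETTERS, 3, replace = TRUE), collapse = ""), ""),
    seq_len(n)),
  uniprot  = function(n) paste0(sample(c("P", "Q", "O"), n, replace = TRUE),
                                sprintf("%05d", sample(10000:99999, n))),
  pdb      = function(n) toupper(format(as.hexmode(sample(4096:65535, n)))),
  prosite  = function(n) sprintf("PS%05d", sample(1:99999, n)),
  interpro = function(n) sprintf("IPR%06d", sample(1:999999, n)),
  pharmgkb = function(n) sprintf("PA%05d", sample(1:99999, n)),
  entrez   = function(n) as.character(sample(1000:999999, n)),
  pubmed   = function(n) sprintf("%08d", sample(10000000:99999999, n)))

withFixtureSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## The fixture "world": every entity and link all sources are views of.
fixtureWorld <- function(spec) {
  withFixtureSeed(spec@randomSeed, {
    D <- spec@nDiseases
    diseases <- data.frame(omim = fixtureIds$omim(D),
                           name = paste("Hereditary syndrome", seq_len(D)),
                           mesh = fixtureIds$mesh(D),
                           orpha = fixtureIds$orphanet(D),
                           stringsAsFactors = FALSE)
    gPer <- drawCounts(D, spec@genesPerDisease)
    G <- sum(gPer)
    genes <- data.frame(symbol = fixtureIds$symbol(G),
                        hgnc = fixtureIds$hgnc(G),
                        omim = rep(diseases$omim, gPer),
                        entrez = fixtureIds$entrez(G),
                        stringsAsFactors = FALSE)
    pPer <- drawCounts(G, spec@proteinsPerGene)
    P <- sum(pPer)
    proteins <- data.frame(acc = fixtureIds$uniprot(P),
                           hgnc = rep(genes$hgnc, pPer),
                           name = paste("Uncharacterized protein", seq_len(P)),
                           stringsAsFactors = FALSE)
    xrefs <- list()
    for (t in XREF_CONCEPTS) {
      xPer <- drawCounts(P, spec@xrefsPerProtein)
      gen <- fixtureIds[[tolower(t)]]
      xrefs[[t]] <- data.frame(id = gen(sum(xPer)),
                               acc = rep(proteins$acc, xPer),
                               stringsAsFactors = FALSE)
    }
    pmPer <- drawCounts(G, c(1L, 2L))
    pubmed <- data.frame(pmid = fixtureIds$pubmed(sum(pmPer)),
                         entrez = rep(genes$entrez, pmPer),
                         stringsAsFactors = FALSE)
    list(diseases = diseases, genes = genes, proteins = proteins,
         xrefs = xrefs, pubmed = pubmed)
  })
}

writeCsv <- function(path, header, rows) {
  quoteField <- function(x) {
    need <- grepl("[\",\n]", x)
    x[need] <- paste0("\"", gsub("\"", "\"\"", x[need]), "\"")
    x
  }
  lines <- c(paste(header, collapse = ","),
             vapply(rows, function(r) paste(quoteField(r), collapse = ","), ""))
  writeLines(lines, path)
  path
}

dfRows <- function(df) lapply(seq_len(nrow(df)), function(i)
  as.character(unlist(df[i, ], use.names = FALSE)))

#' Generate the gene-list CSV fixture
#'
#' A gene-nomenclature-style table: column 0 holds the gene identifier,
#' column 1 the approved symbol. Deterministic under the spec's seed.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @param path Output file; default \code{hgnc.csv} under the output dir.
#' @return list(path, manifest) where manifest records the data-row count
#'   and the distinct-identifier count.
#' @export
generateHgncCsv <- function(spec, path = NULL) {
  world <- fixtureWorld(spec)
  if (is.null(path)) {
    dir.create(spec@outputDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(spec@outputDir, "hgnc.csv")
  }
  g <- world$genes
  writeCsv(path, c("hgnc_id", "approved_symbol"),
           dfRows(g[, c("hgnc", "symbol")]))
  list(path = path,
       manifest = list(rows = nrow(g), distinct_ids = length(unique(g$hgnc))))
}

proteinEntryXML <- function(acc, name, xrefRows) {
  refs <- vapply(seq_len(nrow(xrefRows)), function(i)
    sprintf("    <dbReference type=\"%s\" id=\"%s\"/>",
            xrefRows$type[i], xrefRows$id[i]), "")
  paste(c(sprintf("  <entry accession=\"%s\">", acc),
          sprintf("    <accession>%s</accession>", acc),
          sprintf("    <name>%s</name>", name),
          refs, "  </entry>"), collapse = "\n")
}

#' Generate per-gene protein XML documents
#'
#' One document per gene identifier; each holds an \code{<entry>} node per
#' protein carrying accession, name and cross-reference elements.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @param dir Output directory; default \code{proteins/} under the output
#'   dir.
#' @return list(paths, manifest) with per-document entry and xref counts.
#' @export
generateProteinXml <- function(spec, dir = NULL) {
  world <- fixtureWorld(spec)
  if (is.null(dir)) dir <- file.path(spec@outputDir, "proteins")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  allXrefs <- do.call(rbind, lapply(names(world$xrefs), function(t)
    cbind(world$xrefs[[t]], type = t, stringsAsFactors = FALSE)))
  paths <- character(); manifest <- list()
  for (h in unique(world$proteins$hgnc)) {
    prot <- world$proteins[world$proteins$hgnc == h, , drop = FALSE]
    entries <- vapply(seq_len(nrow(prot)), function(i) {
      xr <- allXrefs[allXrefs$acc == prot$acc[i], , drop = FALSE]
      proteinEntryXML(prot$acc[i], prot$name[i], xr)
    }, "")
    fname <- file.path(dir, paste0(percentEncode(h), ".xml"))
    writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
                 "<proteins>", entries, "</proteins>"), fname)
    paths <- c(paths, fname)
    manifest[[h]] <- list(entries = nrow(prot),
                          xrefs = sum(allXrefs$acc %in% prot$acc))
  }
  list(paths = paths, manifest = manifest)
}

mkSelector <- function(key, query, properties, isKey = FALSE)
  new("Selector", key = key, query = query, properties = properties,
      isKey = isKey)

mkResource <- function(key, kind, concept, selectors, endpoint = "",
                       method = "cache", extends = NA_character_,
                       order = 0L, extras = list())
  new("ResourceDef", key = key, kind = kind, method = method,
      endpoint = endpoint, connectorHint = kind, conceptKey = concept,
      extendsKey = extends, selectors = selectors, order = as.integer(order),
      extras = extras)

fixtureConfig <- function(name = "diseasecard-fixture") {
  new("SeedConfig", name = name, version = "1.0",
      description = "offline rare-disease integration fixture",
      environment = "test",
      baseNamespace = "http://localhost/seed/",
      prefixes = c(kb = "http://localhost/seed/"),
      ontologyImports = character())
}

## Entity grouping of the eleven fixture concepts.
fixtureEntityOf <- c(OMIM = "Disease", MeSH = "Disease", Orphanet = "Disease",
                     HGNC = "Gene", Entrez = "Gene",
                     UniProt = "Protein", PDB = "Protein",
                     PROSITE = "Protein", InterPro = "Protein",
                     PharmGKB = "Protein", PubMed = "Literature")

#' Generate the minimal gene-list seed bundle
#'
#' The simplest configuration: one CSV resource over the gene-list file,
#' with two selectors — column 0 mapped to both dc:source and
#' dc:identifier, column 1 to rdfs:label — so each data row yields two
#' property statements sharing subject and object.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @return list(model, config, setupPath, configPath, csv, manifest).
#' @export
generateMinimalSeed <- function(spec) {
  dir.create(spec@outputDir, showWarnings = FALSE, recursive = TRUE)
  csv <- generateHgncCsv(spec)
  config <- fixtureConfig("gene-list-fixture")
  selectors <- list(
    mkSelector("csv_HGNC_id", "0", c("dc:source", "dc:identifier"),
               isKey = TRUE),
    mkSelector("csv_HGNC_symbol", "1", "rdfs:label"))
  resource <- mkResource("HGNC", "csv", "HGNC", selectors,
                         endpoint = paste0("file://", csv$path))
  model <- new("SeedModel", config = config,
    entities = list(Gene = new("EntityDef", key = "Gene", label = "Gene",
                               conceptKeys = "HGNC")),
    concepts = list(HGNC = new("ConceptDef", key = "HGNC",
                               entityKey = "Gene", label = "HGNC",
                               resourceRefs = "HGNC",
                               bridgeRefs = character())),
    resources = list(HGNC = resource), bridges = list())
  setupPath <- file.path(spec@outputDir, "setup.rdf")
  writeLines(serializeModel(model, "rdfxml"), setupPath)
  configPath <- file.path(spec@outputDir, "config.js")
  writeLines(serializeSeedConfig(config), configPath)
  G <- csv$manifest$rows
  manifest <- list(items = list(HGNC = csv$manifest$distinct_ids),
                   statements = list(HGNC = 3L * G + 2L * G + G),
                   propertyStatementsPerRecord = 2L)
  list(model = model, config = config, setupPath = setupPath,
       configPath = configPath, csv = csv$path, manifest = manifest)
}

#' Generate the full fixture seed bundle
#'
#' Builds the complete offline bundle for the configured concept list:
#' CSV sources (disease map, gene list, literature, terminology), XML
#' cross-reference and per-protein documents, an embedded SQLite protein
#' database, an auxiliary in-process SPARQL endpoint with gene mappings, a
#' mapping list for the map method, the setup graph (RDF/XML), config.js,
#' and a manifest predicting item and statement counts per resource by
#' closed-form arithmetic.
#'
#' The resource chain exercises all three integration methods: cache
#' resources for every concept, two complete resources (gene names by key
#' join; per-protein XML via \code{#replace#}) and one map resource
#' linking proteins to genes.
#'
#' @param spec A \linkS4class{FixtureSpec}.
#' @return list(model, config, setupPath, configPath, registry, manifest,
#'   world, dir).
#' @export
generateFixtureSeed <- function(spec) {
  concepts <- spec@conceptList
  kinds <- c(OMIM = "csv", HGNC = "csv", MeSH = "csv", Orphanet = "csv",
             PubMed = "csv", UniProt = "sql", Entrez = "sparql",
             PDB = "xml", PROSITE = "xml", InterPro = "xml", PharmGKB = "xml")
  if (length(unique(kinds[intersect(concepts, names(kinds))])) < 2L)
    skbStop("seedkb_config_error",
            "fixture concept list must span at least two connector kinds")
  if ("UniProt" %in% concepts && !"HGNC" %in% concepts)
    skbStop("seedkb_config_error",
            "map method requested (UniProt) without its mapping target (HGNC)")
  dir <- spec@outputDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  world <- fixtureWorld(spec)
  D <- nrow(world$diseases); G <- nrow(world$genes); P <- nrow(world$proteins)

  config <- fixtureConfig()
  resources <- list(); items <- list(); statements <- list()
  registry <- EndpointRegistry()

  if ("OMIM" %in% concepts) {
    rows <- lapply(seq_len(G), function(i) {
      d <- world$diseases[world$diseases$omim == world$genes$omim[i], ]
      c(world$genes$omim[i], d$name, world$genes$symbol[i])
    })
    p <- writeCsv(file.path(dir, "omim.csv"),
                  c("omim_id", "disease_name", "gene_symbol"), rows)
    resources$OMIM <- mkResource("OMIM", "csv", "OMIM",
      list(mkSelector("csv_OMIM_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_OMIM_name", "1", "rdfs:label"),
           mkSelector("csv_OMIM_gene", "2", "dc:relation")),
      endpoint = paste0("file://", p), order = 10L)
    items$OMIM <- D
    statements$OMIM <- 3L * D + D + D + G
  }
  if ("HGNC" %in% concepts) {
    p <- generateHgncCsv(spec, file.path(dir, "hgnc.csv"))$path
    resources$HGNC <- mkResource("HGNC", "csv", "HGNC",
      list(mkSelector("csv_HGNC_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_HGNC_symbol", "1", "rdfs:label")),
      endpoint = paste0("file://", p), order = 20L)
    items$HGNC <- G
    statements$HGNC <- 3L * G + G + G
    np <- writeCsv(file.path(dir, "hgnc_names.csv"),
                   c("hgnc_id", "approved_name"),
                   lapply(seq_len(G), function(i)
                     c(world$genes$hgnc[i],
                       paste("gene", world$genes$symbol[i]))))
    resources$HGNC_names <- mkResource("HGNC_names", "csv", "HGNC",
      list(mkSelector("csv_HGNCn_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_HGNCn_name", "1", "dc:description")),
      endpoint = paste0("file://", np), method = "complete",
      extends = "HGNC", order = 30L)
    items$HGNC_names <- 0L
    statements$HGNC_names <- G
  }
  if ("UniProt" %in% concepts) {
    db <- file.path(dir, "proteins.db")
    unlink(db)
    ddl <- c("CREATE TABLE proteins (acc TEXT, gene_hgnc TEXT, name TEXT);",
             sprintf("INSERT INTO proteins VALUES ('%s', '%s', '%s');",
                     world$proteins$acc, world$proteins$hgnc,
                     world$proteins$name))
    sqlQuery(db, paste(ddl, collapse = "\n"), mode = "script")
    resources$UniProt <- mkResource("UniProt", "sql", "UniProt",
      list(mkSelector("sql_UP_acc", "acc", "dc:identifier", isKey = TRUE),
           mkSelector("sql_UP_gene", "gene_hgnc", "dc:relation")),
      endpoint = paste0("sqlite:///", db), order = 40L,
      extras = list("seed:queryText" = "SELECT acc, gene_hgnc FROM proteins"))
    items$UniProt <- P
    statements$UniProt <- 4L * P + P + P
    ## per-protein detail documents for the #replace# complete method
    pdir <- file.path(dir, "uniprot")
    dir.create(pdir, showWarnings = FALSE)
    for (i in seq_len(P))
      writeLines(c("<?xml version=\"1.0\"?>", "<proteins>",
                   proteinEntryXML(world$proteins$acc[i],
                                   world$proteins$name[i],
                                   data.frame(type = character(),
                                              id = character())),
                   "</proteins>"),
                 file.path(pdir, paste0(world$proteins$acc[i], ".xml")))
    resources$UniProt_details <- mkResource("UniProt_details", "xml",
      "UniProt",
      list(mkSelector("xml_UPd_acc", ".//accession/text()", "dc:identifier",
                      isKey = TRUE),
           mkSelector("xml_UPd_name", ".//name/text()", "dc:title")),
      endpoint = paste0("file://", pdir, "/#replace#.xml"),
      method = "complete", extends = "UniProt", order = 50L,
      extras = list("seed:recordPath" = "/*"))
    items$UniProt_details <- 0L
    statements$UniProt_details <- P
    ## protein-gene mapping list for the map method
    mp <- writeCsv(file.path(dir, "map_uniprot_hgnc.csv"),
                   c("acc", "hgnc_id"),
                   dfRows(world$proteins[, c("acc", "hgnc")]))
    resources$UniProt2HGNC <- mkResource("UniProt2HGNC", "csv", "UniProt",
      list(mkSelector("csv_map_acc", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_map_hgnc", "1", "seed:isAssociatedTo")),
      endpoint = paste0("file://", mp), method = "map", extends = "HGNC",
      order = 45L)
    items$UniProt2HGNC <- 0L
    statements$UniProt2HGNC <- 2L * P
  }
  xrefOrder <- 60L
  for (t in intersect(XREF_CONCEPTS, concepts)) {
    xr <- world$xrefs[[t]]
    xp <- file.path(dir, paste0(tolower(t), ".xml"))
    writeLines(c("<?xml version=\"1.0\"?>", "<xrefs>",
                 sprintf("  <xref type=\"%s\" id=\"%s\" protein=\"%s\"/>",
                         t, xr$id, xr$acc),
                 "</xrefs>"), xp)
    resources[[t]] <- mkResource(t, "xml", t,
      list(mkSelector(paste0("xml_", t, "_id"), "@id", "dc:identifier",
                      isKey = TRUE),
           mkSelector(paste0("xml_", t, "_protein"), "@protein",
                      "dc:relation")),
      endpoint = paste0("file://", xp), order = xrefOrder,
      extras = list("seed:recordPath" = sprintf("//xref[@type='%s']", t)))
    xrefOrder <- xrefOrder + 1L
    items[[t]] <- nrow(xr)
    statements[[t]] <- 4L * nrow(xr) + 2L * nrow(xr)
  }
  if ("Entrez" %in% concepts) {
    ## auxiliary seed exposing gene mappings over SPARQL
    aux <- KnowledgeBase()
    auxNS <- "http://localhost/genemap/"
    for (i in seq_len(G)) {
      gu <- paste0(auxNS, "gene_", i)
      addStatements(aux, rbind(
        makeStatements(gu, paste0(auxNS, "entrez"), world$genes$entrez[i]),
        makeStatements(gu, paste0(auxNS, "omim"), world$genes$omim[i])))
    }
    epURI <- "endpoint:genemap"
    registerEndpoint(registry, epURI, aux)
    q <- paste0("PREFIX gm: <", auxNS, ">\n",
                "SELECT ?id ?omim WHERE { ?g gm:entrez ?id . ?g gm:omim ?omim }")
    resources$Entrez <- mkResource("Entrez", "sparql", "Entrez",
      list(mkSelector("sparql_EZ_id", "id", "dc:identifier", isKey = TRUE),
           mkSelector("sparql_EZ_omim", "omim", "dc:relation")),
      endpoint = epURI, order = 70L,
      extras = list("seed:queryText" = q))
    items$Entrez <- G
    statements$Entrez <- 4L * G + G + G
  }
  if ("PubMed" %in% concepts) {
    p <- writeCsv(file.path(dir, "pubmed.csv"), c("pmid", "entrez_id"),
                  dfRows(world$pubmed))
    resources$PubMed <- mkResource("PubMed", "csv", "PubMed",
      list(mkSelector("csv_PM_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_PM_entrez", "1", "dc:relation")),
      endpoint = paste0("file://", p), order = 80L)
    items$PubMed <- nrow(world$pubmed)
    statements$PubMed <- 6L * nrow(world$pubmed)
  }
  if ("MeSH" %in% concepts) {
    p <- writeCsv(file.path(dir, "mesh.csv"), c("mesh_id", "omim_id"),
                  dfRows(world$diseases[, c("mesh", "omim")]))
    resources$MeSH <- mkResource("MeSH", "csv", "MeSH",
      list(mkSelector("csv_MH_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_MH_omim", "1", "dc:relation")),
      endpoint = paste0("file://", p), order = 90L)
    items$MeSH <- D
    statements$MeSH <- 6L * D
  }
  if ("Orphanet" %in% concepts) {
    p <- writeCsv(file.path(dir, "orphanet.csv"),
                  c("orpha_id", "omim_id", "name"),
                  dfRows(world$diseases[, c("orpha", "omim", "name")]))
    resources$Orphanet <- mkResource("Orphanet", "csv", "Orphanet",
      list(mkSelector("csv_OR_id", "0", "dc:identifier", isKey = TRUE),
           mkSelector("csv_OR_omim", "1", "dc:relation"),
           mkSelector("csv_OR_name", "2", "rdfs:label")),
      endpoint = paste0("file://", p), order = 95L)
    items$Orphanet <- D
    statements$Orphanet <- 6L * D
  }

  present <- intersect(concepts, names(fixtureEntityOf))
  entities <- list()
  for (e in unique(fixtureEntityOf[present])) {
    entities[[e]] <- new("EntityDef", key = e, label = e,
                         conceptKeys = present[fixtureEntityOf[present] == e])
  }
  conceptDefs <- list()
  for (ck in present) {
    refs <- names(resources)[vapply(resources, function(r)
      identical(r@conceptKey, ck), TRUE)]
    conceptDefs[[ck]] <- new("ConceptDef", key = ck,
      entityKey = unname(fixtureEntityOf[[ck]]), label = ck,
      resourceRefs = refs,
      bridgeRefs = if (ck == "UniProt") "UniProt" else character())
  }
  bridges <- list()
  if ("UniProt" %in% present)
    bridges$UniProt <- new("BridgeDef", key = "UniProt",
                           conceptKey = "UniProt",
                           pattern = "http://www.uniprot.org/uniprot/#replace#",
                           extraProperties = list())
  model <- new("SeedModel", config = config, entities = entities,
               concepts = conceptDefs, resources = resources,
               bridges = bridges)
  setupPath <- file.path(dir, "setup.rdf")
  writeLines(serializeModel(model, "rdfxml"), setupPath)
  configPath <- file.path(dir, "config.js")
  writeLines(serializeSeedConfig(config), configPath)
  manifest <- list(items = items, statements = statements,
                   links = if ("UniProt" %in% concepts) P else 0L,
                   concepts = length(present))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(model = model, config = config, setupPath = setupPath,
       configPath = configPath, registry = registry, manifest = manifest,
       world = world, dir = dir)
}

#' Register built seed bundles as in-process SPARQL endpoints
#'
#' One endpoint per bundle, each an independent graph; returns the endpoint
#' URIs. Registrations are released with \code{\link{releaseEndpoint}}.
#'
#' @param kbs Named list of \linkS4class{KnowledgeBase} objects (names
#'   become endpoint labels).
#' @param registry An \code{\link{EndpointRegistry}}; created when NULL.
#' @return list(uris, registry).
#' @export
spawnTestEndpoints <- function(kbs, registry = NULL) {
  if (is.null(registry)) registry <- EndpointRegistry()
  uris <- character()
  for (nm in names(kbs)) {
    uri <- paste0("endpoint:", nm)
    registerEndpoint(registry, uri, kbs[[nm]])
    uris <- c(uris, uri)
  }
  list(uris = uris, registry = registry)
}

#' Build the three-endpoint federation fixture
#'
#' Reproduces the distributed-query topology: endpoint 1 holds gene
#' labels, endpoint 2 gene-to-protein links, endpoint 3 protein-to-PDB and
#' protein-to-MeSH links. The returned query asks, across the three
#' services, for the PDB and MeSH identifiers associated with a gene
#' symbol; \code{defederatedQuery} is the same pattern without SERVICE
#' clauses, for execution against the union graph.
#'
#' @param randomSeed Integer seed.
#' @param geneSymbol Gene the query is anchored on; default the fixture's
#'   first gene.
#' @return list(registry, uris, kbs, query, defederatedQuery, geneSymbol,
#'   expected) — expected holds the closed-form (pdb, mesh) pair count.
#' @export
federationFixture <- function(randomSeed = 1L, geneSymbol = NULL) {
  world <- fixtureWorld(fixtureSpec(randomSeed = randomSeed))
  nsA <- "http://localhost/fed/diseasome/"
  nsB <- "http://localhost/fed/genes/"
  nsC <- "http://localhost/fed/proteins/"
  kbA <- KnowledgeBase(); kbB <- KnowledgeBase(); kbC <- KnowledgeBase()
  for (i in seq_len(nrow(world$genes))) {
    gu <- paste0(nsA, "gene_", percentEncode(world$genes$hgnc[i]))
    addStatements(kbA, makeStatements(gu, rdfsLabel(), world$genes$symbol[i]))
    gu2 <- paste0(nsB, "gene_", percentEncode(world$genes$hgnc[i]))
    addStatements(kbB, makeStatements(gu2, dcTerm("title"), world$genes$symbol[i]))
  }
  for (i in seq_len(nrow(world$proteins))) {
    gu2 <- paste0(nsB, "gene_", percentEncode(world$proteins$hgnc[i]))
    pu <- paste0(nsC, "uniprot_", world$proteins$acc[i])
    addStatements(kbB, makeStatements(gu2, seedTerm("isAssociatedTo"), pu,
                                      "uri", graph = ""))
  }
  pdb <- world$xrefs$PDB
  for (i in seq_len(nrow(pdb))) {
    pu <- paste0(nsC, "uniprot_", pdb$acc[i])
    addStatements(kbC, makeStatements(pu, dcTerm("relation"), pdb$id[i]))
  }
  ## one MeSH term per protein, inherited from the disease of its gene
  meshOf <- stats::setNames(world$diseases$mesh, world$diseases$omim)
  omimOf <- stats::setNames(world$genes$omim, world$genes$hgnc)
  for (i in seq_len(nrow(world$proteins))) {
    pu <- paste0(nsC, "uniprot_", world$proteins$acc[i])
    m <- meshOf[[omimOf[[world$proteins$hgnc[i]]]]]
    addStatements(kbC, makeStatements(pu, dcTerm("subject"), m))
  }
  if (is.null(geneSymbol)) geneSymbol <- world$genes$symbol[[1L]]
  ep <- spawnTestEndpoints(list(diseasome = kbA, genes = kbB, proteins = kbC))
  patterns <- c(
    sprintf("?gene <%s> ?label . FILTER (?label = \"%s\")", rdfsLabel(),
            geneSymbol),
    sprintf("?gene2 <%s> ?label . ?gene2 <%s> ?uniprot", dcTerm("title"),
            seedTerm("isAssociatedTo")),
    sprintf("?uniprot <%s> ?pdb . ?uniprot <%s> ?mesh",
            dcTerm("relation"), dcTerm("subject")))
  query <- paste0("SELECT ?pdb ?mesh WHERE {\n",
                  paste(sprintf("  SERVICE <%s> { %s }", ep$uris, patterns),
                        collapse = "\n"), "\n}")
  defederated <- paste0("SELECT ?pdb ?mesh WHERE {\n  ",
                        paste(patterns, collapse = " .\n  "), "\n}")
  gi <- world$genes$symbol == geneSymbol
  accs <- world$proteins$acc[world$proteins$hgnc %in% world$genes$hgnc[gi]]
  expected <- sum(pdb$acc %in% accs)  # one mesh per protein
  list(registry = ep$registry, uris = ep$uris,
       kbs = list(diseasome = kbA, genes = kbB, proteins = kbC),
       query = query, defederatedQuery = defederated,
       geneSymbol = geneSymbol, expected = expected)
}
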