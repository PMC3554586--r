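## Shared helpers: tiny in-code fixtures and independent brute-force
## oracles kept deliberately separate from the implementation paths they
## check.

skey <- function(st) seedkb:::statementKey(st)

## A two-entity proteomics-style model built directly in code.
proteomicsModel <- function() {
  config <- new("SeedConfig", name = "proteomics", version = "1",
                description = "", environment = "test",
                baseNamespace = "http://localhost/seed/",
                prefixes = c(kb = "http://localhost/seed/"))
  sel <- function(key, q, props, isKey = FALSE)
    new("Selector", key = key, query = q, properties = props, isKey = isKey)
  res <- function(key, kind, concept, sels, method = "cache",
                  extends = NA_character_, order = 0L, endpoint = "")
    new("ResourceDef", key = key, kind = kind, method = method,
        endpoint = endpoint, connectorHint = kind, conceptKey = concept,
        extendsKey = extends, selectors = sels, order = as.integer(order),
        extras = list())
  new("SeedModel", config = config,
    entities = list(
      Protein = new("EntityDef", key = "Protein", label = "Protein",
                    conceptKeys = "UniProt"),
      Disease = new("EntityDef", key = "Disease", label = "Disease",
                    conceptKeys = "OMIM")),
    concepts = list(
      UniProt = new("ConceptDef", key = "UniProt", entityKey = "Protein",
                    label = "UniProt", resourceRefs = "UniProt",
                    bridgeRefs = "UniProt"),
      OMIM = new("ConceptDef", key = "OMIM", entityKey = "Disease",
                 label = "OMIM", resourceRefs = "OMIM",
                 bridgeRefs = character())),
    resources = list(
      UniProt = res("UniProt", "csv", "UniProt",
                    list(sel("csv_up_id", "0", "dc:identifier", TRUE),
                         sel("csv_up_name", "1", "rdfs:label"))),
      OMIM = res("OMIM", "csv", "OMIM",
                 list(sel("csv_om_id", "0", "dc:identifier", TRUE)))),
    bridges = list(
      UniProt = new("BridgeDef", key = "UniProt", conceptKey = "UniProt",
                    pattern = "http://www.uniprot.org/uniprot/#replace#",
                    extraProperties = list())))
}

## The simple gene-list scenario: one CSV resource, two selectors (column
## 0 mapped to dc:source + dc:identifier, column 1 to rdfs:label).
geneListModel <- function(csvPath) {
  b <- proteomicsModel()
  sel1 <- new("Selector", key = "csv_HGNC_id", query = "0",
              properties = c("dc:source", "dc:identifier"), isKey = TRUE)
  sel2 <- new("Selector", key = "csv_HGNC_symbol", query = "1",
              properties = "rdfs:label")
  resource <- new("ResourceDef", key = "HGNC", kind = "csv",
                  method = "cache", endpoint = paste0("file://", csvPath),
                  connectorHint = "csv", conceptKey = "HGNC",
                  extendsKey = NA_character_,
                  selectors = list(sel1, sel2), order = 0L, extras = list())
  new("SeedModel", config = b@config,
    entities = list(Gene = new("EntityDef", key = "Gene", label = "Gene",
                               conceptKeys = "HGNC")),
    concepts = list(HGNC = new("ConceptDef", key = "HGNC",
                               entityKey = "Gene", label = "HGNC",
                               resourceRefs = "HGNC",
                               bridgeRefs = character())),
    resources = list(HGNC = resource), bridges = list())
}

writeTempCsv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

## Brute-force topological-order enumeration for graphs of <= 6 nodes:
## every permutation is tested against the dependency edges directly.
allTopoOrders <- function(nodes, after) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], p)
    out
  }
  valid <- list()
  for (p in perms(nodes)) {
    ok <- TRUE
    for (k in names(after))
      for (dep in after[[k]])
        if (match(k, p) < match(dep, p)) { ok <- FALSE; break }
    if (ok) valid[[length(valid) + 1L]] <- p
  }
  valid
}

## Independent statement counter for a cache resource over parsed CSV
## rows: cross-products counted by explicit loops, with set semantics
## emulated through a character set.
bruteCacheCount <- function(rows, selectors, conceptKey, conceptLabel, ns) {
  seen <- character()
  addOnce <- function(key) {
    if (key %in% seen) return(0L)
    seen <<- c(seen, key); 1L
  }
  keySel <- Filter(function(s) s@isKey, selectors)[[1L]]
  total <- 0L
  for (row in rows) {
    id <- row[[as.integer(keySel@query) + 1L]]
    if (!nzchar(id)) next
    item <- paste0(ns, tolower(conceptKey), "_",
                   utils::URLencode(id, reserved = TRUE))
    total <- total + addOnce(paste(item, "type"))
    total <- total + addOnce(paste(item, "hasConcept"))
    total <- total + addOnce(paste(item, "isConceptOf-mirror"))
    labelled <- any(vapply(selectors, function(s)
      "rdfs:label" %in% s@properties &&
        nzchar(row[[as.integer(s@query) + 1L]]), TRUE))
    if (!labelled)
      total <- total + addOnce(paste(item, "label"))
    for (s in selectors) {
      v <- row[[as.integer(s@query) + 1L]]
      if (!nzchar(v)) next
      for (p in s@properties)
        total <- total + addOnce(paste(item, p, v))
    }
  }
  total
}

expectNoSkips <- function(report) {
  expect_equal(sum(report@resources$skips), 0L)
  expect_false(any(report@resources$failed))
}
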