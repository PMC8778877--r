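#' Default medical property filter
#'
#' The 32 Wikidata property identifiers (MeSH, Drugbank, Disease Ontology,
#' eMedicine and similar medical index properties) whose presence on an
#' entity marks it as belonging to the medical domain. User-overridable
#' wherever it is consumed.
#'
#' @return Character vector of 32 property ids.
#' @export
medical_property_filter <- function() {
  c("P636", "P673", "P486", "P715", "P699", "P780", "P923", "P924", "P2452",
    "P1748", "P557", "P2892", "P4338", "P3550", "P3841", "P4495", "P5270",
    "P1694", "P1693", "P1554", "P1550", "P1323", "P696", "P595", "P494",
    "P1692", "P1461", "P667", "P2275", "P4250", "P2176", "P1995")
}

#' Is an entity medical?
#'
#' @param entity_properties Character vector of property ids present on an
#'   entity.
#' @param property_filter The filter set (default
#'   [medical_property_filter()]).
#' @return `TRUE` iff at least one filter property is present.
#' @export
is_medical <- function(entity_properties, property_filter = medical_property_filter()) {
  any(entity_properties %in% property_filter)
}

#' Fetch medical entities from a SPARQL endpoint
#'
#' Optional online path: queries a Wikidata-style SPARQL endpoint for
#' entities carrying any property of `property_filter`, together with their
#' label in `language_code`, aliases, and the three inheritance relations
#' (instance of P31, subclass of P279, part of P361). Entities without a
#' label in the target language are dropped. All tests and the offline
#' pipeline use fixture records instead; `query_fun` exists so the HTTP
#' layer can be replaced (it receives the query string and must return the
#' SPARQL JSON text).
#'
#' @param endpoint_url SPARQL endpoint URL.
#' @param property_filter Property ids (default [medical_property_filter()]).
#' @param language_code Label language (default `"ru"`).
#' @param query_fun Function `(query) -> JSON text`; defaults to HTTP GET.
#' @return List of entity records (see [build_kb()]).
#' @export
fetch_entities <- function(endpoint_url, property_filter = medical_property_filter(),
                           language_code = "ru", query_fun = NULL) {
  query <- sparql_entity_query(property_filter, language_code)
  if (is.null(query_fun)) {
    query_fun <- function(q) {
      url <- paste0(endpoint_url, "?format=json&query=", utils::URLencode(q, reserved = TRUE))
      txt <- tryCatch(paste(readLines(url, warn = FALSE, encoding = "UTF-8"),
                            collapse = "\n"),
                      error = function(e) stop(errorCondition(
                        paste0("SPARQL request failed (retryable): ", conditionMessage(e)),
                        class = c("syntrep_network_error", "error", "condition"))))
      txt
    }
  }
  parse_sparql_entities(query_fun(query), language_code)
}

sparql_entity_query <- function(property_filter, language_code) {
  props <- paste(sprintf("wdt:%s", property_filter), collapse = "|")
  sprintf(paste0(
    "SELECT ?item ?itemLabel ?alias ?instanceOf ?subclassOf ?partOf WHERE { ",
    "?item %s ?idx . ",
    "OPTIONAL { ?item rdfs:label ?itemLabel . FILTER(LANG(?itemLabel) = \"%s\") } ",
    "OPTIONAL { ?item skos:altLabel ?alias . FILTER(LANG(?alias) = \"%s\") } ",
    "OPTIONAL { ?item wdt:P31 ?instanceOf } ",
    "OPTIONAL { ?item wdt:P279 ?subclassOf } ",
    "OPTIONAL { ?item wdt:P361 ?partOf } }"),
    props, language_code, language_code)
}

#' Parse SPARQL JSON bindings into entity records
#'
#' Pure function behind [fetch_entities()]: takes the standard SPARQL JSON
#' results document, aggregates bindings per entity, and keeps only
#' entities with a label in `language_code`.
#'
#' @param json_text SPARQL JSON results as text.
#' @param language_code Required label language.
#' @return List of records: each a list with `qid`, `name`, `aliases`,
#'   `instance_of`, `subclass_of`, `part_of`, `properties`.
#' @export
parse_sparql_entities <- function(json_text, language_code = "ru") {
  doc <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = FALSE),
                  error = function(e) stop(errorCondition(
                    paste0("malformed SPARQL response: ", conditionMessage(e)),
                    class = c("syntrep_format_error", "error", "condition"))))
  bindings <- doc$results$bindings
  if (is.null(bindings)) stop(errorCondition(
    "malformed SPARQL response: no results.bindings",
    class = c("syntrep_format_error", "error", "condition")))
  recs <- new.env(parent = emptyenv())
  val <- function(b, k) if (!is.null(b[[k]])) b[[k]]$value else NULL
  qid_of <- function(uri) sub(".*[/#]", "", uri)
  for (b in bindings) {
    item <- val(b, "item")
    if (is.null(item)) next
    qid <- qid_of(item)
    r <- recs[[qid]]
    if (is.null(r))
      r <- list(qid = qid, name = NA_character_, aliases = character(),
                instance_of = character(), subclass_of = character(),
                part_of = character(), properties = character())
    lab <- b[["itemLabel"]]
    if (!is.null(lab) && (is.null(lab[["xml:lang"]]) || lab[["xml:lang"]] == language_code))
      r$name <- lab$value
    if (!is.null(val(b, "alias"))) r$aliases <- union(r$aliases, val(b, "alias"))
    if (!is.null(val(b, "instanceOf")))
      r$instance_of <- union(r$instance_of, qid_of(val(b, "instanceOf")))
    if (!is.null(val(b, "subclassOf")))
      r$subclass_of <- union(r$subclass_of, qid_of(val(b, "subclassOf")))
    if (!is.null(val(b, "partOf")))
      r$part_of <- union(r$part_of, qid_of(val(b, "partOf")))
    recs[[qid]] <- r
  }
  out <- lapply(sort(ls(recs)), function(q) recs[[q]])
  out[!vapply(out, function(r) is.na(r$name), logical(1))]
}

#' Entity record constructor
#'
#' Convenience for building knowledge-base records in code (fixtures,
#' tests, or file loaders).
#'
#' @param qid Identifier matching `"Q"` + digits.
#' @param name Entity name in the knowledge-base language, or `NA` for an
#'   entity known only as a relation target without a translated label.
#' @param aliases Character vector of synonyms.
#' @param instance_of,subclass_of,part_of Character vectors of target qids.
#' @param properties Property ids present on the entity.
#' @return A record list consumable by [build_kb()].
#' @export
kb_record <- function(qid, name, aliases = character(), instance_of = character(),
                      subclass_of = character(), part_of = character(),
                      properties = character()) {
  if (!grepl("^Q[0-9]+$", qid)) stop("malformed qid: ", qid)
  list(qid = qid, name = name, aliases = aliases, instance_of = instance_of,
       subclass_of = subclass_of, part_of = part_of, properties = properties)
}

#' Build the medical knowledge base store
#'
#' Assembles the two-table store: an entity table (qid, name, normalized
#' name, and the three inheritance relations `instance_of`, `subclass_of`,
#' `part_of`) and a synonym table (alias, normalized alias, target qid).
#' Names and aliases are normalized with [normalize_text()]; synonyms whose
#' target qid is absent are dropped with a warning; duplicate qids with
#' conflicting names are an error.
#'
#' @param records List of records (see [kb_record()],
#'   [parse_sparql_entities()]).
#' @param language_code Language tag stored with the KB (default `"ru"`).
#' @return A `medical_kb`: list with `entities` (data frame with
#'   list-columns for the relations), `synonyms` (data frame), and
#'   `language`.
#' @export
build_kb <- function(records, language_code = "ru") {
  qids <- vapply(records, `[[`, character(1), "qid")
  if (anyDuplicated(qids)) {
    for (q in unique(qids[duplicated(qids)])) {
      names_q <- unique(vapply(records[qids == q], function(r)
        as.character(r$name), character(1)))
      names_q <- names_q[!is.na(names_q)]
      if (length(names_q) > 1)
        stop("duplicate qid ", q, " with conflicting names: ",
             paste(names_q, collapse = " / "))
    }
    records <- records[!duplicated(qids)]
    qids <- qids[!duplicated(qids)]
  }
  name <- vapply(records, function(r) as.character(r$name), character(1))
  entities <- data.frame(qid = qids, name = name,
                         normalized_name = ifelse(is.na(name), NA_character_,
                                                  normalize_text(name)),
                         stringsAsFactors = FALSE)
  entities$instance_of <- lapply(records, function(r) as.character(r$instance_of))
  entities$subclass_of <- lapply(records, function(r) as.character(r$subclass_of))
  entities$part_of <- lapply(records, function(r) as.character(r$part_of))
  syn <- list()
  for (r in records) {
    for (a in r$aliases)
      syn[[length(syn) + 1L]] <- data.frame(alias = a,
                                            normalized_alias = normalize_text(a),
                                            target_qid = r$qid,
                                            stringsAsFactors = FALSE)
  }
  synonyms <- if (length(syn)) do.call(rbind, syn) else
    data.frame(alias = character(), normalized_alias = character(),
               target_qid = character(), stringsAsFactors = FALSE)
  dangling <- !synonyms$target_qid %in% entities$qid
  if (any(dangling)) {
    warning("dropping ", sum(dangling), " synonym(s) with unknown target qid")
    synonyms <- synonyms[!dangling, , drop = FALSE]
    rownames(synonyms) <- NULL
  }
  kb <- structure(list(entities = entities, synonyms = synonyms,
                       language = language_code), class = "medical_kb")
  kb$name_index <- build_phrase_index(entities$normalized_name, entities$qid)
  kb$alias_index <- build_phrase_index(synonyms$normalized_alias,
                                       synonyms$target_qid)
  kb
}

# hash map phrase -> qids, so per-phrase lookup is O(1)
build_phrase_index <- function(phrases, qids) {
  env <- new.env(parent = emptyenv())
  ok <- !is.na(phrases) & nzchar(phrases)
  for (i in which(ok)) env[[phrases[i]]] <- unique(c(env[[phrases[i]]], qids[i]))
  env
}

#' @export
print.medical_kb <- function(x, ...) {
  cat(sprintf("<medical_kb (%s): %d entities, %d synonyms>\n", x$language,
              nrow(x$entities), nrow(x$synonyms)))
  invisible(x)
}

#' Exact-match lookup of a phrase in the knowledge base
#'
#' Matches a normalized phrase against entity names and synonym aliases.
#' All matches are returned; ambiguity is resolved downstream by
#' [disambiguate()].
#'
#' @param kb A `medical_kb`.
#' @param phrase Normalized string (see [normalize_text()]).
#' @return Data frame with columns `qid` and `matched_via`
#'   (`"name"`/`"synonym"`), name matches first, then by qid.
#' @export
lookup_candidates <- function(kb, phrase) {
  hit <- lookup_qids(kb, phrase)
  data.frame(qid = hit$qid, matched_via = hit$via, stringsAsFactors = FALSE)
}

# allocation-free fast path used in the labeling loop
lookup_qids <- function(kb, phrase) {
  if (!is.null(kb$name_index)) {
    by_name <- kb$name_index[[phrase]]
    by_syn <- kb$alias_index[[phrase]]
    if (is.null(by_name) && is.null(by_syn))
      return(list(qid = character(), via = character()))
    if (is.null(by_name)) by_name <- character()
    if (is.null(by_syn)) by_syn <- character()
  } else {
    by_name <- kb$entities$qid[!is.na(kb$entities$normalized_name) &
                                 kb$entities$normalized_name == phrase]
    by_syn <- kb$synonyms$target_qid[kb$synonyms$normalized_alias == phrase]
  }
  by_syn <- setdiff(unique(by_syn), by_name)
  list(qid = c(sort(by_name), sort(by_syn)),
       via = c(rep("name", length(by_name)), rep("synonym", length(by_syn))))
}

#' Resolve an entity's category by relation precedence
#'
#' Follows the inheritance relations in the order *instance of* (closest),
#' *subclass of*, *part of* (most abstract) and returns the names of the
#' first relation's targets that are present in the store with a name in
#' the KB language. Relations often carry several targets; all named target
#' names of the winning relation are returned as co-labels.
#'
#' @param kb A `medical_kb`.
#' @param qid Entity qid (must be in the KB).
#' @return List with `labels` (character vector of category names) and
#'   `relation` (`"instance_of"`, `"subclass_of"` or `"part_of"`), or
#'   `NULL` when no relation target is named.
#' @export
resolve_category <- function(kb, qid) {
  i <- match(qid, kb$entities$qid)
  if (is.na(i)) stop("entity ", qid, " not in knowledge base")
  for (rel in c("instance_of", "subclass_of", "part_of")) {
    targets <- kb$entities[[rel]][[i]]
    if (!length(targets)) next
    j <- match(targets, kb$entities$qid)
    names_t <- kb$entities$name[j]
    names_t <- names_t[!is.na(j) & !is.na(names_t)]
    if (length(names_t)) return(list(labels = unique(names_t), relation = rel))
  }
  NULL
}

#' Load a domain vocabulary
#'
#' One term per line, UTF-8; terms are normalized and deduplicated.
#' Vocabularies carry one of the four fixed categories used for labeling.
#'
#' @param path File path, or a character vector of terms.
#' @param category One of `"Disease"`, `"Sign and symptom"`,
#'   `"Medication"`, `"Physician specialization"`.
#' @return A `domain_vocabulary`: list with `category` and `terms`.
#' @export
load_vocabulary <- function(path, category) {
  categories <- c("Disease", "Sign and symptom", "Medication",
                  "Physician specialization")
  if (!category %in% categories)
    stop("unknown category '", category, "'; must be one of: ",
         paste(categories, collapse = ", "))
  terms <- if (length(path) == 1 && file.exists(path))
    readLines(path, encoding = "UTF-8", warn = FALSE) else path
  terms <- unique(normalize_text(terms))
  terms <- terms[nzchar(terms)]
  structure(list(category = category, terms = terms), class = "domain_vocabulary")
}

#' @export
print.domain_vocabulary <- function(x, ...) {
  cat(sprintf("<domain_vocabulary '%s': %d terms>\n", x$category, length(x$terms)))
  invisible(x)
}

#' Persist / load a knowledge base as JSON Lines tables
#'
#' Two flat, diffable files mirroring the store schema:
#' `entities.jsonl` with keys `qid`, `name`, `normalized_name`,
#' `instance_of`, `subclass_of`, `part_of`, and `synonyms.jsonl` with
#' `alias`, `normalized_alias`, `target_qid`.
#'
#' @param kb A `medical_kb`.
#' @param dir Directory to write into (created if missing).
#' @return The directory (writer) or a `medical_kb` (reader).
#' @export
kb_write <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "entities.jsonl"), open = "wb")
  for (i in seq_len(nrow(kb$entities))) {
    e <- kb$entities[i, ]
    writeLines(jsonlite::toJSON(list(
      qid = e$qid, name = e$name, normalized_name = e$normalized_name,
      instance_of = e$instance_of[[1]], subclass_of = e$subclass_of[[1]],
      part_of = e$part_of[[1]]), auto_unbox = TRUE, digits = NA, null = "null",
      na = "null"), con, useBytes = TRUE)
  }
  close(con)
  write_jsonl(kb$synonyms, file.path(dir, "synonyms.jsonl"))
  invisible(dir)
}

#' @rdname kb_write
#' @param language_code Language tag for the loaded KB.
#' @export
kb_read <- function(dir, language_code = "ru") {
  ent_lines <- readLines(file.path(dir, "entities.jsonl"), encoding = "UTF-8",
                         warn = FALSE)
  records <- lapply(ent_lines, function(l) {
    e <- jsonlite::fromJSON(l)
    kb_record(e$qid, if (is.null(e$name)) NA_character_ else e$name,
              instance_of = as.character(unlist(e$instance_of)),
              subclass_of = as.character(unlist(e$subclass_of)),
              part_of = as.character(unlist(e$part_of)))
  })
  kb <- build_kb(records, language_code)
  syn_path <- file.path(dir, "synonyms.jsonl")
  if (file.exists(syn_path)) {
    syn_lines <- readLines(syn_path, encoding = "UTF-8", warn = FALSE)
    if (length(syn_lines)) {
      syn <- do.call(rbind, lapply(syn_lines, function(l) {
        s <- jsonlite::fromJSON(l)
        data.frame(alias = s$alias, normalized_alias = s$normalized_alias,
                   target_qid = s$target_qid, stringsAsFactors = FALSE)
      }))
      syn <- syn[syn$target_qid %in% kb$entities$qid, , drop = FALSE]
      rownames(syn) <- NULL
      kb$synonyms <- syn
    }
  }
  kb
}
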