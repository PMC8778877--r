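group_label_row <- function(group_id, label_text, source, relation = "none",
                            matched_term = NA_character_,
                            entity_qid = NA_character_) {
  data.frame(group_id = group_id, label_text = label_text, source = source,
             relation = relation, matched_term = matched_term,
             entity_qid = entity_qid, stringsAsFactors = FALSE)
}

empty_labels <- function() {
  data.frame(group_id = character(), label_text = character(),
             source = character(), relation = character(),
             matched_term = character(), entity_qid = character(),
             stringsAsFactors = FALSE)
}

#' Label a group with domain vocabularies
#'
#' A group gets the label `"Disease"`, `"Sign and symptom"`,
#' `"Medication"` or `"Physician specialization"` when one of its repeats
#' contains a term of the corresponding vocabulary. Multiword vocabulary
#' terms match contiguous subsequences of a repeat's normalized lemma
#' sequence.
#'
#' @param group A `repeat_group` with sequences restored
#'   ([restore_sequences()]).
#' @param vocabularies List of `domain_vocabulary` objects.
#' @return Data frame of labels, one row per (category, matched term).
#' @export
label_with_vocabulary <- function(group, vocabularies) {
  out <- list()
  for (voc in vocabularies) {
    if (!length(voc$terms)) next
    hits <- character()
    for (r in group$repeats) {
      lem <- r$lemmas
      for (term in voc$terms) {
        tw <- strsplit(term, " ", fixed = TRUE)[[1]]
        k <- length(tw)
        if (k > length(lem)) next
        if (k == 1) {
          if (term %in% lem) hits <- c(hits, term)
        } else {
          for (s in seq_len(length(lem) - k + 1))
            if (identical(lem[s:(s + k - 1)], tw)) hits <- c(hits, term)
        }
      }
    }
    for (term in sort(unique(hits)))
      out[[length(out) + 1L]] <- group_label_row(group$group_id, voc$category,
                                                 "vocabulary", matched_term = term)
  }
  if (length(out)) do.call(rbind, out) else empty_labels()
}

#' Default date patterns
#'
#' Regular expressions (matched against each repeat's normalized surface
#' and lemma sequence) covering four-digit years 1900-2099, numeric
#' dd.mm.yyyy-style dates, and "day month" phrases with English or Russian
#' month names. Language-dependent; supply your own list for other
#' languages.
#'
#' @return Character vector of regexes.
#' @export
default_date_patterns <- function() {
  months <- paste0(
    "january|february|march|april|may|june|july|august|september|october|",
    "november|december|",
    "январ|феврал|",
    "март|апрел|май|",
    "мая|июн|июл|",
    "август|сентябр|",
    "октябр|ноябр|",
    "декабр")
  c("(^|[^0-9])(19|20)[0-9]{2}([^0-9]|$)",
    "[0-9]{1,2}[./-][0-9]{1,2}[./-][0-9]{2,4}",
    sprintf("(^|\\s)[0-9]{1,2}\\s+(%s)", months),
    sprintf("(^|\\s)(%s)\\w*\\s+[0-9]{1,2}(\\s|$)", months))
}

#' Does a group contain a date designation?
#'
#' @param group A restored `repeat_group`.
#' @param date_patterns Regex list (default [default_date_patterns()]).
#' @return `TRUE` iff any repeat's surface or lemma sequence matches any
#'   pattern; such groups get a `"Timestamp"` label.
#' @export
detect_timestamp <- function(group, date_patterns = default_date_patterns()) {
  norm <- group$surface_norm
  if (is.null(norm))
    norm <- normalize_text(vapply(group$repeats, `[[`, character(1), "surface"))
  texts <- c(norm, vapply(group$repeats, function(r)
    paste(r$lemmas, collapse = " "), character(1)))
  for (p in date_patterns)
    if (any(grepl(p, texts, perl = TRUE, ignore.case = TRUE))) return(TRUE)
  FALSE
}

#' Default event-verb lexicon
#'
#' Passive voice is the primary event signal; the lexicon extends it with
#' verbs that mark a patient event even in active morphology. Ships with
#' the canonical admission/assignment/discharge verbs (English and
#' Russian) plus "identify".
#'
#' @return Character vector of normalized verb lemmas.
#' @export
default_event_lexicon <- function() {
  c("hospitalize", "appoint", "discharge", "identify",
    "госпитализировать",
    "назначить",
    "выписать",
    "выявить")
}

#' Does a group describe an event?
#'
#' `TRUE` when any member token is a verb in passive voice
#' (`Voice=Pass`), or a verb whose lemma is in the event lexicon; such
#' groups get an `"Event"` label.
#'
#' @param group A restored `repeat_group`.
#' @param event_lexicon Normalized verb lemmas (default
#'   [default_event_lexicon()]).
#' @return Logical.
#' @export
detect_event <- function(group, event_lexicon = default_event_lexicon()) {
  for (r in group$repeats) {
    verb <- r$upos == "VERB"
    if (any(verb & grepl("Voice=Pass", r$feats, fixed = TRUE))) return(TRUE)
    if (any(verb & r$lemmas %in% event_lexicon)) return(TRUE)
  }
  FALSE
}

#' Candidate phrases for knowledge-base matching
#'
#' Collects the group's distinct noun and adjective lemmas and returns all
#' their k-permutations (k = 1..`max_words`) joined by single spaces — the
#' strings matched against entity names and synonyms. Permutations (rather
#' than the original order) absorb free word order.
#'
#' @param group A restored `repeat_group`.
#' @param max_words Maximum phrase length (default 3).
#' @return Character vector of normalized phrases, deduplicated, shortest
#'   first.
#' @export
candidate_phrases <- function(group, max_words = 3) {
  lem <- unique(unlist(lapply(group$repeats, function(r)
    r$lemmas[r$upos %in% c("NOUN", "PROPN", "ADJ")])))
  lem <- sort(lem[nzchar(lem)])
  if (!length(lem)) return(character())
  out <- character()
  perms <- function(prefix, remaining, depth) {
    for (i in seq_along(remaining)) {
      phrase <- c(prefix, remaining[i])
      out[[length(out) + 1L]] <<- paste(phrase, collapse = " ")
      if (depth > 1) perms(phrase, remaining[-i], depth - 1L)
    }
  }
  perms(character(), lem, min(max_words, length(lem)))
  unique(out[order(lengths(strsplit(out, " ", fixed = TRUE)), out)])
}

#' Train linking embeddings on the KB graph + forest union
#'
#' Builds one undirected graph whose vertices are strings: normalized
#' entity names, aliases, and forest lemmas. KB edges follow the three
#' inheritance relations (name to named target name) and alias-to-entity
#' links; forest edges connect parent and child lemmas. Shared vocabulary
#' joins the two components, so corpus context and knowledge-base topology
#' land in one vector space. Walks use the dedicated linking defaults
#' (p = 1, q = 2, 3 walks per start, length 5) and feed a skip-gram model.
#'
#' @param kb A `medical_kb`.
#' @param forest Optional `joined_forest`; `NULL` trains on the KB graph
#'   alone.
#' @param config A [walk_config()]; defaults to the linking parameters.
#' @param dimension,window,epochs,min_count Passed to
#'   [train_embeddings()].
#' @return An `embedding_space` over the union vocabulary.
#' @export
train_kb_embeddings <- function(kb, forest = NULL,
                                config = walk_config(p = 1, q = 2,
                                                     walks_per_start = 3,
                                                     walk_length = 5),
                                dimension = 100, window = 5, epochs = 5,
                                min_count = 1) {
  edges <- list()
  ent <- kb$entities
  named <- !is.na(ent$normalized_name)
  for (i in which(named)) {
    for (rel in c("instance_of", "subclass_of", "part_of")) {
      j <- match(ent[[rel]][[i]], ent$qid)
      j <- j[!is.na(j)]
      tn <- ent$normalized_name[j]
      tn <- tn[!is.na(tn)]
      if (length(tn))
        edges[[length(edges) + 1L]] <- cbind(ent$normalized_name[i], tn)
    }
  }
  if (nrow(kb$synonyms)) {
    j <- match(kb$synonyms$target_qid, ent$qid)
    ok <- !is.na(ent$normalized_name[j])
    if (any(ok))
      edges[[length(edges) + 1L]] <- cbind(kb$synonyms$normalized_alias[ok],
                                           ent$normalized_name[j][ok])
  }
  if (!is.null(forest)) {
    nd <- forest$nodes
    keep_node <- stats::setNames(!nd$is_added & nd$id != forest$virtual_root, nd$id)
    ed <- forest$edges
    ok <- keep_node[as.character(ed$parent)] & keep_node[as.character(ed$child)]
    if (any(ok)) {
      lem <- stats::setNames(nd$lemma, nd$id)
      edges[[length(edges) + 1L]] <- cbind(lem[as.character(ed$parent[ok])],
                                           lem[as.character(ed$child[ok])])
    }
  }
  if (!length(edges)) stop("empty union graph: no named KB edges and no forest")
  em <- do.call(rbind, edges)
  em <- em[em[, 1] != em[, 2], , drop = FALSE]
  em <- unique(em)
  if (!nrow(em)) stop("empty union graph: no usable edges")
  labels <- sort(unique(as.vector(em)))
  a <- match(em[, 1], labels)
  b <- match(em[, 2], labels)
  neigh <- vector("list", length(labels))
  sp <- split(c(b, a), c(a, b))
  for (k in names(sp)) neigh[[as.integer(k)]] <- unique(sp[[k]])
  wts <- lapply(neigh, function(x) rep(1, length(x)))
  g <- walk_graph(labels = labels, neigh = neigh, wts = wts,
                  emit = rep(TRUE, length(labels)),
                  starts = which(lengths(neigh) > 0))
  walks <- with_seed(config$seed, walk_corpus(g, config))
  train_embeddings(walks, mode = "skipgram", dimension = dimension,
                   window = window, epochs = epochs, seed = config$seed,
                   min_count = min_count)
}

#' Pick an entity among ambiguous candidates
#'
#' The decision rule for aliases pointing at several entities: choose the
#' candidate whose category name has the highest cosine similarity to the
#' term being labeled, in the linking embedding space. Candidates whose
#' category name (or the term itself) is out of vocabulary rank last; ties
#' break by qid order. When nothing is in vocabulary the first candidate by
#' qid is returned flagged low-confidence.
#'
#' @param term Normalized term being labeled.
#' @param candidates Data frame with columns `qid` and `category_name`.
#' @param space An `embedding_space` (from [train_kb_embeddings()]).
#' @return List: `qid`, `category_name`, `score` (`NA` if out of
#'   vocabulary), `low_confidence`.
#' @export
disambiguate <- function(term, candidates, space) {
  if (!nrow(candidates)) stop("empty candidate list")
  vocab <- rownames(space$vectors)
  score <- rep(NA_real_, nrow(candidates))
  if (term %in% vocab) {
    inv <- candidates$category_name %in% vocab
    score[inv] <- vapply(candidates$category_name[inv], function(cn)
      cosine_similarity(space, term, cn), numeric(1))
  }
  o <- order(-ifelse(is.na(score), -Inf, score), candidates$qid)
  best <- o[1]
  list(qid = candidates$qid[best], category_name = candidates$category_name[best],
       score = score[best], low_confidence = all(is.na(score)))
}

#' Label a group with knowledge-base categories
#'
#' Matches the group's candidate phrases ([candidate_phrases()]) against
#' entity names and synonyms; ambiguous matches are settled by
#' [disambiguate()]; the winning entity's category is resolved by relation
#' precedence ([resolve_category()]) and all co-label names of the winning
#' relation are emitted.
#'
#' @param group A restored `repeat_group`.
#' @param kb A `medical_kb`.
#' @param space Linking `embedding_space` (may be `NULL`: ambiguity then
#'   falls back to qid order).
#' @param max_words Phrase length bound (default 3).
#' @return Data frame of labels with `source = "wikidata"` and the relation
#'   recorded.
#' @export
label_with_kb <- function(group, kb, space = NULL, max_words = 3) {
  out <- list()
  for (phrase in candidate_phrases(group, max_words)) {
    hit <- lookup_qids(kb, phrase)
    if (!length(hit$qid)) next
    cats <- lapply(hit$qid, function(q) resolve_category(kb, q))
    ok <- !vapply(cats, is.null, logical(1))
    if (!any(ok)) next
    qids <- hit$qid[ok]
    cats <- cats[ok]
    if (length(qids) > 1) {
      cd <- data.frame(qid = qids,
                       category_name = normalize_text(
                         vapply(cats, function(x) x$labels[[1]], character(1))),
                       stringsAsFactors = FALSE)
      pick <- if (is.null(space)) list(qid = sort(cd$qid)[1]) else
        disambiguate(phrase, cd, space)
      sel <- match(pick$qid, qids)
    } else {
      sel <- 1L
    }
    res <- cats[[sel]]
    for (lab in res$labels)
      out[[length(out) + 1L]] <- group_label_row(
        group$group_id, lab, "wikidata", relation = res$relation,
        matched_term = phrase, entity_qid = qids[sel])
  }
  if (length(out)) do.call(rbind, out) else empty_labels()
}

#' Annotate repeat groups and compute the coverage report
#'
#' Applies the labeling sources in order — domain vocabularies, timestamp
#' detection, event detection, knowledge-base categories — and assembles
#' the corpus report. A sentence counts as covered when some group
#' containing one of its repeats holds at least one label.
#'
#' @param groups A restored `repeat_groups` list.
#' @param kb A `medical_kb` (or `NULL` to skip KB labeling).
#' @param vocabularies List of `domain_vocabulary` objects.
#' @param space Linking `embedding_space` or `NULL`.
#' @param sentence_ids Character vector of all corpus sentence ids (the
#'   coverage denominator).
#' @param max_words Phrase length bound for KB matching.
#' @param date_patterns,event_lexicon Heuristic configuration.
#' @return List with `labels` (data frame) and `report`
#'   (an `annotation_report`).
#' @export
annotate_groups <- function(groups, kb, vocabularies, space, sentence_ids,
                            max_words = 3,
                            date_patterns = default_date_patterns(),
                            event_lexicon = default_event_lexicon()) {
  labs <- list(empty_labels())
  for (g in groups) {
    labs[[length(labs) + 1L]] <- label_with_vocabulary(g, vocabularies)
    if (detect_timestamp(g, date_patterns))
      labs[[length(labs) + 1L]] <- group_label_row(g$group_id, "Timestamp",
                                                   "timestamp")
    if (detect_event(g, event_lexicon))
      labs[[length(labs) + 1L]] <- group_label_row(g$group_id, "Event", "event")
    if (!is.null(kb))
      labs[[length(labs) + 1L]] <- label_with_kb(g, kb, space, max_words)
  }
  labels <- do.call(rbind, labs)
  rownames(labels) <- NULL
  list(labels = labels,
       report = make_report(groups, labels, sentence_ids))
}

#' Assemble the annotation report
#'
#' @param groups A `repeat_groups` list.
#' @param labels Label data frame (see [annotate_groups()]).
#' @param sentence_ids All corpus sentence ids.
#' @return An `annotation_report`: sentence coverage, per-source label
#'   counts, label frequency table, and the group histograms of
#'   [group_statistics()].
#' @export
make_report <- function(groups, labels, sentence_ids) {
  labeled_groups <- unique(labels$group_id)
  covered <- character()
  for (g in groups) {
    if (!g$group_id %in% labeled_groups) next
    covered <- union(covered, vapply(g$repeats, `[[`, character(1), "sentence_id"))
  }
  covered <- intersect(covered, sentence_ids)
  total <- length(sentence_ids)
  freq <- sort(table(labels$label_text), decreasing = TRUE)
  structure(list(
    sentences_total = total,
    sentences_covered = length(covered),
    coverage_fraction = if (total) length(covered) / total else 0,
    groups_total = length(groups),
    groups_labeled = length(labeled_groups),
    source_counts = table_to_int(labels$source),
    label_freq = stats::setNames(as.integer(freq), names(freq)),
    group_stats = group_statistics(groups)), class = "annotation_report")
}

#' @export
print.annotation_report <- function(x, ...) {
  cat(sprintf(paste0("<annotation_report: %d/%d sentences covered (%.1f%%), ",
                     "%d/%d groups labeled>\n"),
              x$sentences_covered, x$sentences_total, 100 * x$coverage_fraction,
              x$groups_labeled, x$groups_total))
  if (length(x$source_counts)) {
    cat("labels by source:",
        paste(names(x$source_counts), x$source_counts, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Export labels as JSON Lines
#'
#' @param labels Label data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path) {
  write_jsonl(labels, path)
}
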