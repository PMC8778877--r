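#' Graft synonym nodes into the forest
#'
#' For every original, non-stopword node whose lemma has embedding
#' neighbors above `threshold`, adds one new node per neighbor at the same
#' place in the tree: the added node carries the synonym lemma, hangs off
#' the same parent with the same relation and weight, and is linked to the
#' same children as the source node (children are shared, not copied, so a
#' synonym can head the same partial subtree the original heads). With the
#' trees extended this way, similar-subtree search reduces to equal-subtree
#' search. Added nodes are flagged `is_added`, never start walks, and never
#' count toward repeat word length; synonyms of added nodes are never
#' expanded.
#'
#' @param forest An encoded `joined_forest`.
#' @param space An `embedding_space`.
#' @param threshold Cosine similarity cut-off in (0, 1\].
#' @param max_synonyms Fan-out guard: at most this many (the most similar)
#'   synonym nodes are grafted per source node. On well-trained spaces few
#'   words exceed the threshold and the guard is inert; on tiny or
#'   degenerate corpora it keeps the subsequent search tractable.
#' @return List with `forest` (augmented) and `provenance` (data frame:
#'   `added_id`, `source_id`, `synonym_lemma`, `similarity`). Idempotent:
#'   re-running on the result adds nothing.
#' @export
extend_forest <- function(forest, space, threshold = 0.75, max_synonyms = 10) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  if (is.null(forest$codec)) stop("forest must be encoded first (see encode_forest)")
  nd <- forest$nodes
  existing <- paste(nd$source[nd$is_added], nd$lemma[nd$is_added])
  vocab <- rownames(space$vectors)
  targets <- which(!nd$is_added & !nd$excluded & nd$id != forest$virtual_root &
                     nd$lemma %in% vocab)
  # neighbor lists per distinct lemma, queried once
  lemmas <- unique(nd$lemma[targets])
  nn <- lapply(lemmas, function(l)
    utils::head(nearest_neighbors(space, l, threshold), max_synonyms))
  names(nn) <- lemmas
  capped <- mean(vapply(nn, nrow, integer(1)) >= max_synonyms)
  if (length(nn) > 10 && capped > 0.5)
    warning(sprintf(paste0("%.0f%% of lemmas hit the max_synonyms cap; the ",
                           "embedding space looks degenerate (corpus too ",
                           "small?) and downstream search may be slow"),
                    100 * capped), call. = FALSE)
  new_nodes <- list()
  new_edges <- list()
  prov <- list()
  next_id <- max(nd$id)
  for (i in targets) {
    hits <- nn[[nd$lemma[i]]]
    if (!nrow(hits)) next
    for (k in seq_len(nrow(hits))) {
      syn <- hits$word[k]
      if (paste(nd$id[i], syn) %in% existing) next
      next_id <- next_id + 1L
      new_nodes[[length(new_nodes) + 1L]] <- data.frame(
        id = next_id, lemma = syn, form = syn, upos = nd$upos[i],
        feats = nd$feats[i], sentence_id = nd$sentence_id[i], index = NA_integer_,
        is_added = TRUE, excluded = TRUE, source = nd$id[i],
        code = codec_encode(forest$codec, syn), stringsAsFactors = FALSE)
      ein <- forest$edges[forest$edges$child == nd$id[i], , drop = FALSE]
      kids <- forest$children_of[[nd$id[i]]]
      new_edges[[length(new_edges) + 1L]] <- rbind(
        data.frame(parent = ein$parent, child = next_id, relation = ein$relation,
                   weight = ein$weight, stringsAsFactors = FALSE),
        if (length(kids)) data.frame(
          parent = next_id, child = kids,
          relation = forest$edges$relation[match(kids, forest$edges$child)],
          weight = forest$edges$weight[match(kids, forest$edges$child)],
          stringsAsFactors = FALSE))
      prov[[length(prov) + 1L]] <- data.frame(
        added_id = next_id, source_id = nd$id[i], synonym_lemma = syn,
        similarity = hits$similarity[k], stringsAsFactors = FALSE)
    }
  }
  if (length(new_nodes)) {
    forest$nodes <- rbind(forest$nodes, do.call(rbind, new_nodes))
    forest$edges <- rbind(forest$edges, do.call(rbind, new_edges))
    forest <- rebuild_adjacency(forest)
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(added_id = integer(), source_id = integer(),
               synonym_lemma = character(), similarity = numeric(),
               stringsAsFactors = FALSE)
  list(forest = forest, provenance = provenance)
}

#' Write a synonym-node provenance map as JSON Lines
#'
#' @param provenance The provenance data frame from [extend_forest()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  write_jsonl(provenance, path)
}

write_jsonl <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(df)) {
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]), auto_unbox = TRUE,
                                  digits = NA),
                 con, useBytes = TRUE)
  }
  invisible(path)
}
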