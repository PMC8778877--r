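#' Join sentence trees under a virtual root
#'
#' Builds the corpus-wide forest the mining and walk algorithms traverse:
#' every sentence root becomes a child of one artificial virtual-root node,
#' so the whole corpus is a single tree. Edges carry the dependency relation
#' and a numeric weight looked up from `weight_map` (default 1 for
#' unlisted relations); virtual-root edges use the reserved relation
#' `"virtualroot"` with weight 1.
#'
#' @param trees List of `sentence_tree` objects with unique sentence ids.
#' @param weight_map Optional named numeric vector (relation label ->
#'   positive weight), or a two-column data frame / TSV path (label, weight).
#' @return A `joined_forest`: list with `nodes` (data frame: `id`, `lemma`
#'   (normalized), `form`, `upos`, `feats`, `sentence_id`, `index`,
#'   `is_added`, `excluded`, `source`, `code`), `edges` (data frame:
#'   `parent`, `child`, `relation`, `weight`), `virtual_root` (id 1), and
#'   derived adjacency (`parent_of`, `children_of`).
#' @export
build_joined_forest <- function(trees, weight_map = NULL) {
  wm <- load_weight_map(weight_map)
  sids <- vapply(trees, `[[`, character(1), "sentence_id")
  if (anyDuplicated(sids))
    stop("duplicate sentence ids: ", paste(unique(sids[duplicated(sids)]), collapse = ", "))
  nodes <- list(virtual_root_node())
  edges <- list()
  offset <- 1L
  for (tr in trees) {
    tk <- tr$tokens
    n <- nrow(tk)
    ids <- offset + seq_len(n)
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = ids, lemma = normalize_text(tk$lemma), form = tk$form, upos = tk$upos,
      feats = tk$feats, sentence_id = tr$sentence_id, index = tk$index,
      is_added = FALSE, excluded = tk$excluded, source = NA_integer_,
      code = NA_integer_, stringsAsFactors = FALSE)
    parent <- ifelse(tk$head == 0L, 1L, offset + tk$head)
    rel <- ifelse(tk$head == 0L, "virtualroot", tk$deprel)
    w <- ifelse(tk$head == 0L, 1.0, lookup_weight(wm, tk$deprel))
    edges[[length(edges) + 1L]] <- data.frame(
      parent = parent, child = ids, relation = rel, weight = w,
      stringsAsFactors = FALSE)
    offset <- offset + n
  }
  forest <- structure(list(
    nodes = do.call(rbind, nodes),
    edges = if (length(edges)) do.call(rbind, edges) else
      data.frame(parent = integer(), child = integer(), relation = character(),
                 weight = numeric(), stringsAsFactors = FALSE),
    virtual_root = 1L), class = "joined_forest")
  rebuild_adjacency(forest)
}

virtual_root_node <- function() {
  data.frame(id = 1L, lemma = "<root>", form = "<root>", upos = "X", feats = "_",
             sentence_id = NA_character_, index = NA_integer_, is_added = FALSE,
             excluded = TRUE, source = NA_integer_, code = NA_integer_,
             stringsAsFactors = FALSE)
}

load_weight_map <- function(weight_map) {
  if (is.null(weight_map)) return(numeric())
  if (is.character(weight_map) && length(weight_map) == 1 && file.exists(weight_map)) {
    tab <- utils::read.delim(weight_map, header = FALSE, stringsAsFactors = FALSE)
    weight_map <- stats::setNames(as.numeric(tab[[2]]), tab[[1]])
  }
  if (is.data.frame(weight_map))
    weight_map <- stats::setNames(as.numeric(weight_map[[2]]), weight_map[[1]])
  if (any(weight_map <= 0)) stop("edge weights must be positive")
  weight_map
}

lookup_weight <- function(wm, relations) {
  if (!length(wm)) return(rep(1.0, length(relations)))
  w <- unname(wm[relations])
  w[is.na(w)] <- 1.0
  w
}

rebuild_adjacency <- function(forest) {
  n_ids <- max(forest$nodes$id)
  parent_of <- rep(NA_integer_, n_ids)
  parent_of[forest$edges$child] <- forest$edges$parent
  children_of <- vector("list", n_ids)
  if (nrow(forest$edges)) {
    sp <- split(forest$edges$child, forest$edges$parent)
    children_of[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  forest$parent_of <- parent_of
  forest$children_of <- children_of
  forest
}

#' @export
print.joined_forest <- function(x, ...) {
  cat(sprintf("<joined_forest: %d nodes (%d added), %d sentences>\n",
              nrow(x$nodes), sum(x$nodes$is_added),
              length(unique(stats::na.omit(x$nodes$sentence_id)))))
  invisible(x)
}

#' Per-node height arrays
#'
#' For every node, computes one height entry per child: entry *i* is the
#' node's height when all child subtrees except the *i*-th are excluded,
#' i.e. `1 + height(child_i)`. Leaves get the single entry 0, and the
#' maximum of a node's array is its classical height (edge-counting). These
#' arrays let a phrase be matched at whatever depth it occurs in a
#' sentence.
#'
#' @param forest A `joined_forest`.
#' @return Named list: `arrays` (list indexed by node id) and `height`
#'   (integer vector of classical heights indexed by node id).
#' @export
compute_height_arrays <- function(forest) {
  ids <- forest$nodes$id
  order <- topo_order(forest)
  height <- rep(0L, max(ids))
  arrays <- vector("list", max(ids))
  for (v in rev(order)) {
    ch <- forest$children_of[[v]]
    if (is.null(ch) || !length(ch)) {
      arrays[[v]] <- 0L
      height[v] <- 0L
    } else {
      arrays[[v]] <- 1L + height[ch]
      height[v] <- max(arrays[[v]])
    }
  }
  list(arrays = arrays, height = height)
}

# ids in root-to-leaf order (parents before children)
topo_order <- function(forest) {
  out <- integer(nrow(forest$nodes))
  out[1L] <- forest$virtual_root
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    ch <- forest$children_of[[out[head]]]
    if (length(ch)) {
      out[tail + seq_along(ch)] <- ch
      tail <- tail + length(ch)
    }
    head <- head + 1L
  }
  out[seq_len(tail)]
}

#' Lemma/integer label codec
#'
#' Bijective map between normalized lemmas and integer codes, so subtree
#' comparison works on integers. Codes are assigned on first sight and are
#' stable within a run. Code 0 is reserved for the virtual root and
#' negative codes for repeat-class vertices.
#'
#' @return A `label_codec` (environment-backed).
#' @export
label_codec <- function() {
  env <- new.env(parent = emptyenv())
  env$rev <- character()
  structure(env, class = "label_codec")
}

#' @rdname label_codec
#' @param codec A `label_codec`.
#' @param lemmas Character vector of normalized lemmas.
#' @export
codec_encode <- function(codec, lemmas) {
  codes <- match(lemmas, codec$rev)
  if (anyNA(codes)) {
    codec$rev <- c(codec$rev, unique(lemmas[is.na(codes)]))
    codes <- match(lemmas, codec$rev)
  }
  codes
}

#' @rdname label_codec
#' @param codes Integer vector of codes.
#' @export
codec_decode <- function(codec, codes) {
  out <- rep(NA_character_, length(codes))
  pos <- !is.na(codes) & codes > 0
  out[pos] <- codec$rev[codes[pos]]
  out[!is.na(codes) & codes == 0] <- "<root>"
  out[!is.na(codes) & codes < 0] <- sprintf("<class%d>", -codes[!is.na(codes) & codes < 0])
  out
}

#' Encode forest lemmas as integer codes
#'
#' Assigns every node its lemma's integer code (equal normalized lemmas
#' share one code; added synonym nodes encode their synonym lemma). The
#' codec is attached to the forest for later decoding.
#'
#' @param forest A `joined_forest`.
#' @param codec Optional existing [label_codec()] to extend.
#' @return The forest with `nodes$code` filled and `codec` attached.
#' @export
encode_forest <- function(forest, codec = NULL) {
  if (is.null(codec)) codec <- label_codec()
  code <- codec_encode(codec, forest$nodes$lemma)
  code[forest$nodes$id == forest$virtual_root] <- 0L
  forest$nodes$code <- code
  forest$codec <- codec
  forest
}
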