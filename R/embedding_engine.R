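#' Biased random-walk configuration
#'
#' Parameters of the second-order (node2vec-style) walk. `p` penalizes
#' returning to the node just left, `q` penalizes moving to nodes two steps
#' away from it; `q > p` keeps walks local, which suits syntactic trees.
#' Defaults are the settings used for training the grouping embeddings:
#' p = 2, q = 3, five walks per start node, at most five emitted words per
#' walk. Probabilities are used non-normalized, exactly as given.
#'
#' @param p Positive return parameter.
#' @param q Positive in-out parameter.
#' @param walks_per_start Walks started from every eligible node.
#' @param walk_length Maximum number of emitted tokens per walk.
#' @param seed Integer seed; all walk randomness flows through it.
#' @param cross_sentence Should walks traverse the virtual root between
#'   sentences? The model is trained on the joined tree, so this defaults
#'   to `TRUE`.
#' @return A `walk_config` list.
#' @export
walk_config <- function(p = 2, q = 3, walks_per_start = 5, walk_length = 5,
                        seed = 1L, cross_sentence = TRUE) {
  stopifnot(p > 0, q > 0, walks_per_start >= 1, walk_length >= 1)
  structure(list(p = p, q = q, walks_per_start = as.integer(walks_per_start),
                 walk_length = as.integer(walk_length), seed = as.integer(seed),
                 cross_sentence = isTRUE(cross_sentence)),
            class = "walk_config")
}

#' Second-order step bias
#'
#' The unnormalized bias applied to a candidate next node at shortest-path
#' distance `d` from the previous walk node: `1/p` for d = 0 (return),
#' 1 for d = 1, `1/q` for d = 2.
#'
#' @param d Integer vector with values in {0, 1, 2}.
#' @param config A [walk_config()].
#' @return Numeric vector of biases.
#' @export
step_bias <- function(d, config) {
  if (any(!d %in% 0:2)) stop("d must be in {0, 1, 2}")
  c(1 / config$p, 1, 1 / config$q)[d + 1L]
}

# --- internal walk graph -----------------------------------------------------
# A walk graph is label-agnostic: integer nodes, undirected adjacency with
# per-edge weights, an emit mask and node labels. Both the joined forest and
# the KB-union graph are lowered to this form.
walk_graph <- function(labels, neigh, wts, emit, starts) {
  list(labels = labels, neigh = neigh, wts = wts, emit = emit, starts = starts)
}

forest_walk_graph <- function(forest, config) {
  keep <- !forest$nodes$is_added
  if (!config$cross_sentence) {
    ed <- forest$edges[forest$edges$relation != "virtualroot", , drop = FALSE]
  } else {
    ed <- forest$edges
  }
  ok <- keep[match(ed$parent, forest$nodes$id)] & keep[match(ed$child, forest$nodes$id)]
  ed <- ed[ok, , drop = FALSE]
  n <- max(forest$nodes$id)
  neigh <- vector("list", n)
  wts <- vector("list", n)
  from <- c(ed$parent, ed$child)
  to <- c(ed$child, ed$parent)
  w <- c(ed$weight, ed$weight)
  sp <- split(seq_along(from), from)
  for (k in names(sp)) {
    i <- as.integer(k)
    neigh[[i]] <- to[sp[[k]]]
    wts[[i]] <- w[sp[[k]]]
  }
  nd <- forest$nodes
  emit <- rep(FALSE, n)
  emit[nd$id] <- !nd$excluded & !nd$is_added & nd$id != forest$virtual_root
  walk_graph(labels = replace(rep(NA_character_, n), nd$id, nd$lemma),
             neigh = neigh, wts = wts, emit = emit, starts = which(emit))
}

#' Transition distribution of the biased walk
#'
#' Probability of each neighbor of `current` being the next walk node,
#' proportional to `step_bias(d) * edge_weight` where `d` is the distance
#' from `prev` to the candidate (0 = the previous node itself, 1 = adjacent
#' to it, 2 otherwise). When `prev` is `NULL` (first step) all biases are 1.
#'
#' @param forest An encoded `joined_forest` (or an internal walk graph).
#' @param current Node id with at least one neighbor.
#' @param prev Previous node id or `NULL`.
#' @param config A [walk_config()].
#' @return Named numeric vector of probabilities over neighbor ids, summing
#'   to 1.
#' @export
transition_distribution <- function(forest, current, prev = NULL, config = walk_config()) {
  g <- if (inherits(forest, "joined_forest")) forest_walk_graph(forest, config) else forest
  pr <- transition_probs(g, current, prev, config)
  stats::setNames(pr$prob, pr$nb)
}

transition_probs <- function(g, current, prev, config) {
  nb <- g$neigh[[current]]
  if (is.null(nb) || !length(nb))
    stop("node ", current, " has no neighbors")
  w <- g$wts[[current]]
  if (is.null(prev)) {
    bias <- rep(1, length(nb))
  } else {
    d <- ifelse(nb == prev, 0L, ifelse(nb %in% g$neigh[[prev]], 1L, 2L))
    bias <- step_bias(d, config)
  }
  pr <- bias * w
  list(nb = nb, prob = pr / sum(pr))
}

#' Generate biased random walks over the forest
#'
#' Starts `walks_per_start` walks from every eligible node (original,
#' non-stopword, non-virtual) and follows the second-order transition rule.
#' Stopword and virtual nodes are traversed but never emitted; each walk
#' emits at most `walk_length` tokens. Deterministic for a fixed seed.
#'
#' @param forest An encoded `joined_forest`.
#' @param config A [walk_config()].
#' @return List of character vectors of normalized lemmas (the walk
#'   corpus).
#' @export
generate_walks <- function(forest, config = walk_config()) {
  g <- forest_walk_graph(forest, config)
  with_seed(config$seed, walk_corpus(g, config))
}

walk_corpus <- function(g, config) {
  walks <- vector("list", length(g$starts) * config$walks_per_start)
  k <- 0L
  max_steps <- config$walk_length * 4L
  for (start in g$starts) {
    for (r in seq_len(config$walks_per_start)) {
      cur <- start
      prev <- NULL
      emitted <- character(config$walk_length)
      ne <- 0L
      for (step in seq_len(max_steps)) {
        if (g$emit[cur]) {
          ne <- ne + 1L
          emitted[ne] <- g$labels[cur]
          if (ne == config$walk_length) break
        }
        if (is.null(g$neigh[[cur]]) || !length(g$neigh[[cur]])) break
        pr <- transition_probs(g, cur, prev, config)
        nxt <- pr$nb[sample.int(length(pr$nb), 1L, prob = pr$prob)]
        prev <- cur
        cur <- nxt
      }
      k <- k + 1L
      walks[[k]] <- emitted[seq_len(ne)]
    }
  }
  walks[vapply(walks, length, integer(1)) > 0]
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Train word embeddings on a walk corpus
#'
#' Runs a deterministic single-threaded word2vec trainer (negative
#' sampling) over the walk corpus. `mode = "cbow"` is used for the grouping
#' embeddings, `mode = "skipgram"` for the knowledge-base linking
#' embeddings. Reproducibility contract: fixed seed, one worker, fixed
#' epoch count; neighbor ranks are stable across platforms even if the last
#' ulps of the floats are not.
#'
#' @param walks List of character vectors (from [generate_walks()]).
#' @param mode `"cbow"` or `"skipgram"`.
#' @param dimension Embedding dimension (default 100).
#' @param window Context window (default 5).
#' @param epochs Training epochs (default 5).
#' @param seed Integer seed.
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (default 1; walk corpora are small).
#' @param negative Number of negative samples per update.
#' @param alpha Initial learning rate.
#' @return An `embedding_space`: list with `vectors` (matrix, one row per
#'   word) and `provenance` (named character, `"trained"`/`"pretrained"`).
#' @export
train_embeddings <- function(walks, mode = c("cbow", "skipgram"), dimension = 100,
                             window = 5, epochs = 5, seed = 1L, min_count = 1,
                             negative = 5, alpha = 0.025) {
  mode <- match.arg(mode)
  toks <- unlist(walks, use.names = FALSE)
  if (!length(toks)) stop("empty walk corpus")
  counts <- table(toks)
  counts <- counts[counts >= min_count]
  if (!length(counts)) stop("no token reaches min_count")
  vocab <- names(counts)[order(-as.integer(counts), names(counts))]
  cnt <- as.numeric(counts[vocab])
  idx <- stats::setNames(seq_along(vocab), vocab)
  sentences <- lapply(walks, function(w) {
    v <- idx[w]
    as.integer(v[!is.na(v)]) - 1L
  })
  sentences <- sentences[vapply(sentences, length, integer(1)) > 0]
  mat <- .w2v_train_cpp(sentences, length(vocab), cnt, as.integer(dimension),
                        as.integer(window), as.integer(epochs), alpha,
                        as.integer(negative), mode == "cbow", as.integer(seed))
  rownames(mat) <- vocab
  nrm <- sqrt(rowSums(mat^2))
  if (any(nrm == 0)) {
    warning("dropping ", sum(nrm == 0), " zero vector(s)")
    mat <- mat[nrm > 0, , drop = FALSE]
  }
  embedding_space(mat, provenance = stats::setNames(rep("trained", nrow(mat)),
                                                    rownames(mat)))
}

#' Construct an embedding space from a matrix
#'
#' @param vectors Numeric matrix with one row per word; rownames are the
#'   vocabulary. Zero vectors are rejected.
#' @param provenance Optional named character vector
#'   (`"trained"`/`"pretrained"`).
#' @return An `embedding_space`.
#' @export
embedding_space <- function(vectors, provenance = NULL) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (any(sqrt(rowSums(vectors^2)) == 0)) stop("zero vectors are not allowed")
  if (is.null(provenance))
    provenance <- stats::setNames(rep("trained", nrow(vectors)), rownames(vectors))
  structure(list(vectors = vectors, provenance = provenance),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d words, dimension %d (%d pretrained)>\n",
              nrow(x$vectors), ncol(x$vectors), sum(x$provenance == "pretrained")))
  invisible(x)
}

space_vector <- function(space, word) {
  i <- match(word, rownames(space$vectors))
  if (is.na(i))
    stop(errorCondition(sprintf("word '%s' not in vocabulary", word),
                        class = c("syntrep_oov_error", "error", "condition"),
                        word = word))
  space$vectors[i, ]
}

#' Cosine similarity between two stored words
#'
#' @param space An `embedding_space`.
#' @param a,b Words in the vocabulary (typed lookup error otherwise).
#' @return Cosine of the stored vectors, in \[-1, 1\].
#' @export
cosine_similarity <- function(space, a, b) {
  va <- space_vector(space, a)
  vb <- space_vector(space, b)
  sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
}

#' Most similar words above a threshold
#'
#' Ranks the vocabulary by cosine similarity to `word`, excludes the word
#' itself, keeps entries with similarity strictly above `threshold`
#' (default 0.75, the level used when grafting synonym nodes), and breaks
#' ties lexicographically.
#'
#' @param space An `embedding_space`.
#' @param word Query word (must be in vocabulary).
#' @param threshold Similarity cut-off in (0, 1\].
#' @return Data frame with columns `word` and `similarity`, sorted
#'   descending.
#' @export
nearest_neighbors <- function(space, word, threshold = 0.75) {
  v <- space_vector(space, word)
  m <- space$vectors
  sims <- as.numeric(m %*% v) / (sqrt(rowSums(m^2)) * sqrt(sum(v^2)))
  words <- rownames(m)
  keep <- words != word & sims > threshold
  words <- words[keep]
  sims <- sims[keep]
  o <- order(-sims, words)
  data.frame(word = words[o], similarity = sims[o], stringsAsFactors = FALSE)
}

#' Merge pretrained vectors into a trained space
#'
#' Union of vocabularies; on conflict the trained vector wins. Used to
#' widen the neighbor pool with general-language embeddings (the original
#' setting merged 50k vectors pretrained on fiction).
#'
#' @param space Trained `embedding_space`.
#' @param pretrained An `embedding_space` of equal dimension.
#' @return Merged `embedding_space` with provenance recorded per word.
#' @export
merge_pretrained <- function(space, pretrained) {
  if (ncol(space$vectors) != ncol(pretrained$vectors))
    stop("dimension mismatch: ", ncol(space$vectors), " vs ", ncol(pretrained$vectors))
  new_words <- setdiff(rownames(pretrained$vectors), rownames(space$vectors))
  vectors <- rbind(space$vectors, pretrained$vectors[new_words, , drop = FALSE])
  prov <- c(space$provenance,
            stats::setNames(rep("pretrained", length(new_words)), new_words))
  embedding_space(vectors, prov)
}

#' Read/write word2vec text format
#'
#' Plain-text format: a header line `"<count> <dim>"`, then one word and its
#' floats per line.
#'
#' @param path File path.
#' @param provenance Provenance tag recorded for every word read.
#' @return An `embedding_space` (for the reader); the path, invisibly (for
#'   the writer).
#' @export
read_word2vec <- function(path, provenance = "pretrained") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  n <- hdr[1]
  dim <- hdr[2]
  parts <- strsplit(lines[1 + seq_len(n)], " ", fixed = TRUE)
  words <- vapply(parts, `[[`, character(1), 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(dim)))
  rownames(mat) <- words
  embedding_space(mat, stats::setNames(rep(provenance, n), words))
}

#' @rdname read_word2vec
#' @param space An `embedding_space`.
#' @export
write_word2vec <- function(space, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(space$vectors), ncol(space$vectors)), con,
             useBytes = TRUE)
  rows <- apply(space$vectors, 1, function(r)
    paste(format(r, digits = 8, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(paste(rownames(space$vectors), rows), con, useBytes = TRUE)
  invisible(path)
}
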