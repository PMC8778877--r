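#' Canonical form of a partial subtree
#'
#' The order-independent recursive representation under which two subtrees
#' are equal: a node is rendered as its integer lemma code followed by the
#' sorted list of its children's forms. Sorting the children makes the form
#' invariant under permutation of siblings, which absorbs free word order.
#'
#' @param forest An encoded `joined_forest`.
#' @param root Root node id of the subtree.
#' @param members Integer vector of node ids forming a connected subtree
#'   containing `root`.
#' @return The canonical form as a string, e.g. `"3(1,7(2))"`.
#' @export
canonical_form <- function(forest, root, members) {
  members <- unique(as.integer(members))
  if (!root %in% members) stop("root must be a member")
  inset <- logical(max(forest$nodes$id))
  inset[members] <- TRUE
  for (m in setdiff(members, root)) {
    p <- forest$parent_of[m]
    if (is.na(p) || !inset[p]) stop("members are not a connected subtree")
  }
  code <- code_lookup(forest)
  form_rec <- function(v) {
    ch <- forest$children_of[[v]]
    ch <- ch[inset[ch]]
    if (!length(ch)) return(as.character(code[v]))
    paste0(code[v], "(", paste(sort(vapply(ch, form_rec, character(1))),
                               collapse = ","), ")")
  }
  form_rec(root)
}

code_lookup <- function(forest) {
  code <- rep(NA_integer_, max(forest$nodes$id))
  code[forest$nodes$id] <- forest$nodes$code
  if (anyNA(code[forest$nodes$id])) stop("forest must be encoded first")
  code
}

form_depth <- function(form) {
  chars <- strsplit(form, "", fixed = TRUE)[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (!length(depth)) 0L else max(depth)
}

new_group <- function(canonical, occs, group_id) {
  structure(list(group_id = group_id, canonical = canonical,
                 repeats = occs, class_vertex_ids = integer(),
                 class_vertices = NULL),
            class = "repeat_group")
}

#' @export
print.repeat_group <- function(x, ...) {
  cat(sprintf("<repeat_group %s: %d repeats of %d word(s), form %s>\n",
              x$group_id, length(x$repeats), length(x$repeats[[1]]$members),
              x$canonical))
  invisible(x)
}

#' @export
print.repeat_groups <- function(x, ...) {
  cat(sprintf("<repeat_groups: %d groups>\n", length(x)))
  for (g in utils::head(x, 10)) print(g)
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

original_children <- function(forest) {
  added <- logical(max(forest$nodes$id))
  added[forest$nodes$id] <- forest$nodes$is_added
  lapply(seq_len(max(forest$nodes$id)), function(v) {
    ch <- forest$children_of[[v]]
    if (is.null(ch)) integer() else ch[!added[ch]]
  })
}

descendants <- function(children_of, root) {
  out <- integer()
  frontier <- root
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(children_of[frontier], use.names = FALSE)
  }
  out
}

#' Full-repeat search (base algorithm)
#'
#' Finds groups of *full* subtrees — each includes every node reachable
#' from its root — that occur at least `min_count` times in the joined
#' forest. Nodes are bucketed by classical height and, within a bucket,
#' subtrees with identical canonical forms are grouped. Added synonym
#' nodes are ignored: the base algorithm predates tree extension. Because a
#' full subtree's form pins down its exact shape, this search misses
#' phrases that recur with any extra or missing word, which is what the
#' partial-repeat search ([find_partial_repeats()]) fixes.
#'
#' @param forest An encoded `joined_forest`.
#' @param min_count Minimum number of occurrences (default 2).
#' @return A `repeat_groups` list, ordered by subtree height then canonical
#'   form.
#' @export
find_full_repeats <- function(forest, min_count = 2) {
  nd <- forest$nodes
  real <- nd$id[!nd$is_added & nd$id != forest$virtual_root]
  if (!length(real)) return(structure(list(), class = "repeat_groups"))
  och <- original_children(forest)
  code <- code_lookup(forest)
  ord <- topo_order(forest)
  ord <- ord[ord %in% real]
  form <- character(max(nd$id))
  height <- integer(max(nd$id))
  for (v in rev(ord)) {
    ch <- och[[v]]
    if (!length(ch)) {
      form[v] <- as.character(code[v])
      height[v] <- 0L
    } else {
      form[v] <- paste0(code[v], "(", paste(sort(form[ch]), collapse = ","), ")")
      height[v] <- 1L + max(height[ch])
    }
  }
  sid <- stats::setNames(nd$sentence_id, nd$id)
  groups <- list()
  for (h in sort(unique(height[ord]))) {
    at_h <- ord[height[ord] == h]
    reps <- split(at_h, form[at_h])
    reps <- reps[vapply(reps, length, integer(1)) >= min_count]
    for (f in sort(names(reps))) {
      occs <- lapply(sort(reps[[f]]), function(r) {
        mem <- sort(descendants(och, r))
        list(root = r, members = mem, sentence_id = unname(sid[as.character(r)]))
      })
      groups[[length(groups) + 1L]] <- new_group(f, occs,
                                                 sprintf("f%04d", length(groups) + 1L))
    }
  }
  structure(groups, class = "repeat_groups")
}

#' All non-empty subsets of a node's children
#'
#' The candidate child combinations examined by the partial-repeat search.
#' Deterministic order: by subset size, then by position. Nodes with more
#' than `max_children` children are skipped with a warning (a fan-out guard;
#' set `hard_error = TRUE` to fail instead).
#'
#' @param node_children Vector of child identifiers.
#' @param max_children Fan-out limit (default 8, i.e. at most 255 subsets).
#' @param hard_error Raise an error instead of skipping when the limit is
#'   exceeded.
#' @return List of non-empty subsets (`2^n - 1` of them), or an empty list
#'   when there are no children or the limit is exceeded.
#' @export
enumerate_child_combinations <- function(node_children, max_children = 8,
                                         hard_error = FALSE) {
  n <- length(node_children)
  if (n == 0) return(list())
  if (n > max_children) {
    msg <- sprintf("node with %d children exceeds max_children = %d", n, max_children)
    if (hard_error) stop(msg)
    warning(msg, "; skipping its child combinations", call. = FALSE)
    return(list())
  }
  out <- vector("list", 2^n - 1)
  k <- 0L
  for (size in seq_len(n)) {
    for (comb in utils::combn(n, size, simplify = FALSE)) {
      k <- k + 1L
      out[[k]] <- node_children[comb]
    }
  }
  out
}

#' Partial-repeat search (multi-height algorithm)
#'
#' The modified search: instead of a single height per node, every node
#' contributes candidate subtrees at all the heights its height array
#' induces, built from combinations of its child subtrees, so a phrase is
#' found no matter where in a sentence it sits and even when extra words
#' intervene. If the forest carries added synonym nodes (see
#' [extend_forest()]), each tree position may realize its own lemma or any
#' grafted synonym lemma, so similar — not only equal — phrases fall into
#' one group. Repeated canonical forms (at least `min_count` distinct
#' occurrences, counted per position set; twice within one sentence counts)
#' become groups. For each occurrence a class vertex is materialized with a
#' fresh negative class code, the incoming edge of the occurrence root and
#' outgoing edges to that occurrence's chosen children, which makes the
#' final sequence-restoring traversal trivial.
#'
#' Every full-repeat form of at most `max_len` words is also a partial
#' form, so the output subsumes [find_full_repeats()] up to the length cap.
#'
#' @param forest An encoded `joined_forest`, optionally extended.
#' @param max_len Maximum repeat length in words (original tree positions;
#'   added synonym nodes do not count). Default 5, which keeps groups short
#'   and informative.
#' @param min_count Minimum occurrences per group (default 2).
#' @param max_children Fan-out guard per node (default 8).
#' @param max_forms Guard on the number of synonym-realization forms kept
#'   per candidate subtree (default 256, reached only when many positions
#'   carry many grafted synonyms at once; the most similar realizations are
#'   grafted first, so truncation drops the least plausible ones).
#' @return A `repeat_groups` list ordered by form height then canonical
#'   form, each repeat reported against original sentence nodes.
#' @export
find_partial_repeats <- function(forest, max_len = 5, min_count = 2,
                                 max_children = 8, max_forms = 256) {
  nd <- forest$nodes
  real <- nd$id[!nd$is_added & nd$id != forest$virtual_root]
  if (!length(real)) return(structure(list(), class = "repeat_groups"))
  code <- code_lookup(forest)
  och <- original_children(forest)
  # alternative codes per original position: own code plus grafted synonyms
  alt <- vector("list", max(nd$id))
  for (v in real) alt[[v]] <- as.character(code[v])
  add <- which(nd$is_added)
  for (i in add) {
    s <- nd$source[i]
    alt[[s]] <- unique(c(alt[[s]], as.character(nd$code[i])))
  }
  sid <- stats::setNames(nd$sentence_id, nd$id)
  ord <- topo_order(forest)
  ord <- ord[ord %in% real]

  registry <- new.env(parent = emptyenv())  # form -> list(keys=env, occs=list)
  register <- function(forms, root, members) {
    key <- paste(members, collapse = ",")
    for (f in forms) {
      slot <- registry[[f]]
      if (is.null(slot)) {
        slot <- list(keys = new.env(parent = emptyenv()), occs = list())
      }
      if (is.null(slot$keys[[key]])) {
        slot$keys[[key]] <- TRUE
        slot$occs[[length(slot$occs) + 1L]] <-
          list(root = root, members = members,
               sentence_id = unname(sid[as.character(root)]))
      }
      registry[[f]] <- slot
    }
  }

  sub <- vector("list", max(nd$id))  # per-node candidate entries
  truncated <- FALSE
  for (v in rev(ord)) {
    entries <- list(list(members = v, nwords = 1L, forms = alt[[v]]))
    ch <- och[[v]]
    subsets <- enumerate_child_combinations(ch, max_children)
    for (S in subsets) {
      if (1L + length(S) > max_len) next
      combos <- list(list(members = integer(), nwords = 0L, cf = list()))
      for (si in seq_along(S)) {
        c_id <- S[si]
        slack <- max_len - 1L - (length(S) - si)  # later children need >= 1 word each
        nxt <- list()
        for (cmb in combos) {
          for (e in sub[[c_id]]) {
            nw <- cmb$nwords + e$nwords
            if (nw > slack) next
            nxt[[length(nxt) + 1L]] <- list(members = c(cmb$members, e$members),
                                            nwords = nw,
                                            cf = c(cmb$cf, list(e$forms)))
          }
        }
        combos <- nxt
        if (!length(combos)) break
      }
      for (cmb in combos) {
        joined <- combine_forms(cmb$cf, max_forms)
        forms <- unique(as.vector(outer(alt[[v]], joined,
                                        function(a, j) paste0(a, "(", j, ")"))))
        if (length(forms) > max_forms) {
          truncated <- TRUE
          forms <- forms[seq_len(max_forms)]
        }
        entries[[length(entries) + 1L]] <-
          list(members = sort(c(v, cmb$members)), nwords = 1L + cmb$nwords,
               forms = forms)
      }
    }
    for (e in entries) register(e$forms, v, sort(e$members))
    sub[[v]] <- entries
  }
  if (truncated)
    warning("some candidate subtrees exceeded max_forms = ", max_forms,
            " synonym realizations; least-similar realizations were dropped",
            call. = FALSE)

  forms <- ls(registry)
  keep <- forms[vapply(forms, function(f) length(registry[[f]]$occs), integer(1)) >=
                  min_count]
  if (!length(keep)) return(structure(list(), class = "repeat_groups"))
  depth <- vapply(keep, form_depth, integer(1))
  keep <- keep[order(depth, keep)]
  # synonym realizations of one and the same occurrence set describe one
  # group; keep the first form per occurrence-set signature (without added
  # nodes every occurrence set has exactly one form, so this is a no-op)
  occ_sig <- vapply(keep, function(f)
    paste(sort(vapply(registry[[f]]$occs, function(o)
      paste0(o$root, ":", paste(o$members, collapse = ",")), character(1))),
      collapse = "|"), character(1))
  keep <- keep[!duplicated(occ_sig)]
  groups <- vector("list", length(keep))
  class_counter <- 0L
  for (gi in seq_along(keep)) {
    slot <- registry[[keep[gi]]]
    occs <- slot$occs[order(vapply(slot$occs, `[[`, integer(1), "root"),
                            vapply(slot$occs, function(o)
                              paste(o$members, collapse = ","), character(1)))]
    g <- new_group(keep[gi], occs, sprintf("g%04d", gi))
    cls <- lapply(seq_along(occs), function(j) {
      o <- occs[[j]]
      kids <- intersect(forest$children_of[[o$root]], o$members)
      list(class_id = -(class_counter + j), class_code = -gi,
           parent_id = forest$parent_of[o$root], child_ids = kids)
    })
    class_counter <- class_counter + length(occs)
    g$class_vertices <- cls
    g$class_vertex_ids <- vapply(cls, `[[`, integer(1), "class_id")
    groups[[gi]] <- g
  }
  structure(groups, class = "repeat_groups")
}

# all distinct sorted joins of one form chosen per child slot (capped)
combine_forms <- function(cf, max_forms = 256) {
  if (!length(cf)) return(character())
  if (length(cf) == 1L) return(cf[[1]])
  if (prod(lengths(cf)) > max_forms)
    cf <- lapply(cf, function(x) x[seq_len(min(length(x),
                                               max(1L, max_forms %/% length(cf))))])
  if (length(cf) == 2L) {
    a <- rep(cf[[1]], times = length(cf[[2]]))
    b <- rep(cf[[2]], each = length(cf[[1]]))
    return(unique(ifelse(a <= b, paste(a, b, sep = ","),
                         paste(b, a, sep = ","))))
  }
  grid <- do.call(expand.grid, c(cf, list(stringsAsFactors = FALSE,
                                          KEEP.OUT.ATTRS = FALSE)))
  unique(apply(grid, 1, function(r) paste(sort(unname(r)), collapse = ",")))
}

#' Brute-force oracle for partial repeats
#'
#' Exhaustively enumerates every connected subtree of at most `max_len`
#' nodes rooted at every original node, builds an order-independent form
#' directly from normalized lemmas (no codec, no height machinery), and
#' returns the forms occurring at least `min_count` times. Intended as an
#' independent correctness reference for [find_partial_repeats()] on small
#' forests; added synonym nodes are not modeled.
#'
#' @param forest A `joined_forest` (at most `size_guard` original nodes).
#' @param max_len Maximum subtree size in words.
#' @param min_count Minimum occurrences.
#' @param size_guard Refuse larger forests (default 200 nodes).
#' @return A `repeat_groups` list (lemma-based canonical forms), ordered by
#'   form.
#' @export
oracle_partial_repeats <- function(forest, max_len = 5, min_count = 2,
                                   size_guard = 200) {
  nd <- forest$nodes
  real <- nd$id[!nd$is_added & nd$id != forest$virtual_root]
  if (length(real) > size_guard) stop("forest too large for the brute-force oracle")
  lemma <- stats::setNames(nd$lemma, nd$id)
  sid <- stats::setNames(nd$sentence_id, nd$id)
  och <- original_children(forest)
  # enumerate (form, members) pairs of connected subtrees rooted at v
  memo <- new.env(parent = emptyenv())
  enum <- function(v, budget) {
    mkey <- paste0(v, ":", budget)
    hit <- memo[[mkey]]
    if (!is.null(hit)) return(hit)
    base <- list(list(form = lemma[[as.character(v)]], members = v, n = 1L))
    ch <- och[[v]]
    if (!length(ch) || budget == 1L) {
      memo[[mkey]] <- base
      return(base)
    }
    out <- base
    for (k in seq_len(length(ch))) {
      for (pick in utils::combn(seq_along(ch), k, simplify = FALSE)) {
        S <- ch[pick]
        if (1L + length(S) > budget) next
        parts <- list(list(forms = character(), members = integer(), n = 0L))
        for (c_id in S) {
          sub <- enum(c_id, budget - 1L)
          nxt <- list()
          for (p in parts) for (e in sub) {
            if (1L + p$n + e$n > budget) next
            nxt[[length(nxt) + 1L]] <- list(forms = c(p$forms, e$form),
                                            members = c(p$members, e$members),
                                            n = p$n + e$n)
          }
          parts <- nxt
        }
        for (p in parts) {
          if (length(p$forms) < length(S)) next
          out[[length(out) + 1L]] <- list(
            form = paste0(lemma[[as.character(v)]], "(",
                          paste(sort(p$forms), collapse = ","), ")"),
            members = sort(c(v, p$members)), n = 1L + p$n)
        }
      }
    }
    memo[[mkey]] <- out
    out
  }
  tally <- new.env(parent = emptyenv())
  for (v in real) {
    for (e in enum(v, as.integer(max_len))) {
      key <- paste(e$members, collapse = ",")
      slot <- tally[[e$form]]
      if (is.null(slot)) slot <- list(keys = character(), occs = list())
      if (!key %in% slot$keys) {
        slot$keys <- c(slot$keys, key)
        slot$occs[[length(slot$occs) + 1L]] <-
          list(root = v, members = e$members,
               sentence_id = unname(sid[as.character(v)]))
      }
      tally[[e$form]] <- slot
    }
  }
  forms <- sort(ls(tally))
  keep <- forms[vapply(forms, function(f) length(tally[[f]]$occs), integer(1)) >=
                  min_count]
  groups <- lapply(seq_along(keep), function(i)
    new_group(keep[i], tally[[keep[i]]]$occs, sprintf("o%04d", i)))
  structure(groups, class = "repeat_groups")
}

#' Brute-force oracle for full repeats
#'
#' Enumerates the full subtree below every original node, hashes
#' lemma-based forms, and returns those occurring at least `min_count`
#' times. Correctness reference for [find_full_repeats()].
#'
#' @inheritParams oracle_partial_repeats
#' @return A `repeat_groups` list.
#' @export
oracle_full_repeats <- function(forest, min_count = 2, size_guard = 200) {
  nd <- forest$nodes
  real <- nd$id[!nd$is_added & nd$id != forest$virtual_root]
  if (length(real) > size_guard) stop("forest too large for the brute-force oracle")
  lemma <- stats::setNames(nd$lemma, nd$id)
  sid <- stats::setNames(nd$sentence_id, nd$id)
  och <- original_children(forest)
  form_of <- function(v) {
    ch <- och[[v]]
    if (!length(ch)) return(lemma[[as.character(v)]])
    paste0(lemma[[as.character(v)]], "(",
           paste(sort(vapply(ch, form_of, character(1))), collapse = ","), ")")
  }
  forms <- vapply(real, form_of, character(1))
  reps <- split(real, forms)
  reps <- reps[vapply(reps, length, integer(1)) >= min_count]
  keep <- sort(names(reps))
  groups <- lapply(seq_along(keep), function(i) {
    occs <- lapply(sort(reps[[keep[i]]]), function(r)
      list(root = r, members = sort(descendants(och, r)),
           sentence_id = unname(sid[as.character(r)])))
    new_group(keep[i], occs, sprintf("O%04d", i))
  })
  structure(groups, class = "repeat_groups")
}

#' Restore surface word sequences for repeat groups
#'
#' Fills each repeat with the original sentence material of its members
#' ordered by token index: the surface string, the normalized lemma
#' sequence, POS tags and morphological features (needed downstream by the
#' labeling rules).
#'
#' @param forest The `joined_forest` the groups were mined from.
#' @param groups A `repeat_groups` list.
#' @return The groups with `token_indices`, `surface`, `lemmas`, `upos` and
#'   `feats` filled in per repeat.
#' @export
restore_sequences <- function(forest, groups) {
  nd <- forest$nodes
  row_of <- match(seq_len(max(nd$id)), nd$id)
  idx <- nd$index
  out <- lapply(groups, function(g) {
    g$repeats <- lapply(g$repeats, function(r) {
      rows <- row_of[r$members]
      rows <- rows[order(idx[rows])]
      r$token_indices <- idx[rows]
      r$surface <- paste(nd$form[rows], collapse = " ")
      r$lemmas <- nd$lemma[rows]
      r$upos <- nd$upos[rows]
      r$feats <- nd$feats[rows]
      r
    })
    # one vectorized normalization per group, kept parallel to the repeats
    g$surface_norm <- normalize_text(vapply(g$repeats, `[[`, character(1),
                                            "surface"))
    g
  })
  structure(out, class = "repeat_groups")
}

#' Group histograms
#'
#' The two frequency statistics reported for a mining run: how long the
#' repeats are (words per repeat, one value per group) and how large the
#' groups are (repeats per group).
#'
#' @param groups A `repeat_groups` list.
#' @return List with `length_hist` and `size_hist`, each a named integer
#'   vector (value -> number of groups).
#' @export
group_statistics <- function(groups) {
  if (!length(groups))
    return(list(length_hist = integer(), size_hist = integer()))
  len <- vapply(groups, function(g) length(g$repeats[[1]]$members), integer(1))
  size <- vapply(groups, function(g) length(g$repeats), integer(1))
  list(length_hist = table_to_int(len), size_hist = table_to_int(size))
}

table_to_int <- function(x) {
  t <- table(x)
  stats::setNames(as.integer(t), names(t))
}

#' Export repeat groups as JSON Lines
#'
#' One line per group: `group_id`, `canonical_digest`, and the repeats with
#' sentence id, token indices, and surface.
#'
#' @param groups A `repeat_groups` list (after [restore_sequences()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_groups <- function(groups, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (g in groups) {
    rec <- list(group_id = g$group_id, canonical_digest = g$canonical,
                repeats = lapply(g$repeats, function(r)
                  list(sentence_id = r$sentence_id,
                       token_indices = as.integer(r$token_indices),
                       surface = r$surface)))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}
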