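test_that("canonical form is invariant under child permutation", {
  a <- make_tree("a", c("r", "x", "y"), c(0L, 1L, 1L))
  b <- make_tree("b", c("r", "y", "x"), c(0L, 1L, 1L))
  f <- encode_forest(build_joined_forest(list(a, b)))
  roots <- f$children_of[[f$virtual_root]]
  mem <- lapply(roots, function(r) syntrep:::descendants(
    syntrep:::original_children(f), r))
  expect_identical(canonical_form(f, roots[1], mem[[1]]),
                   canonical_form(f, roots[2], mem[[2]]))
  # single node
  leaf <- f$nodes$id[f$nodes$lemma == "x"][1]
  expect_identical(canonical_form(f, leaf, leaf),
                   as.character(f$nodes$code[f$nodes$id == leaf]))
  expect_error(canonical_form(f, roots[1], c(roots[1], leaf + 100L)),
               "connected")
})

test_that("the shared phrase fragment has one form in both example trees", {
  f <- encode_forest(build_joined_forest(extra_child_trees()))
  inf <- f$nodes$id[f$nodes$lemma == "infarction"]
  myo <- f$nodes$id[f$nodes$lemma == "myocardial"]
  forms <- vapply(1:2, function(i)
    canonical_form(f, inf[i], c(inf[i], myo[i])), character(1))
  expect_identical(forms[1], forms[2])
})

test_that("full search finds nothing on the extra-child pair; partial finds the phrase", {
  f <- encode_forest(build_joined_forest(extra_child_trees()))
  expect_length(find_full_repeats(f), 0L)
  pg <- find_partial_repeats(f)
  expect_gt(length(pg), 0L)
  inf <- f$nodes$id[f$nodes$lemma == "infarction"]
  myo <- f$nodes$id[f$nodes$lemma == "myocardial"]
  two_word <- Filter(function(g) length(g$repeats[[1]]$members) == 2, pg)
  expect_length(two_word, 1L)
  expect_setequal(
    vapply(two_word[[1]]$repeats, function(r) paste(sort(r$members), collapse = ","),
           character(1)),
    vapply(1:2, function(i) paste(sort(c(inf[i], myo[i])), collapse = ","),
           character(1)))
})

test_that("depth-shifted 4-word phrase is found by partial search only", {
  f <- encode_forest(build_joined_forest(depth_shift_trees()))
  expect_length(find_full_repeats(f), 0L)
  pg <- find_partial_repeats(f)
  lem <- stats::setNames(f$nodes$lemma, f$nodes$id)
  four <- Filter(function(g) length(g$repeats[[1]]$members) == 4, pg)
  expect_length(four, 1L)
  for (r in four[[1]]$repeats)
    expect_setequal(unname(lem[as.character(r$members)]),
                    c("assigned", "diagnosis", "diabetes", "mellitus"))
  expect_length(four[[1]]$repeats, 2L)
})

test_that("a verbatim duplicated tree reproduces the full-subtree oracle", {
  tr <- make_tree("d1", c("r", "x", "y", "x"), c(0L, 1L, 2L, 1L))
  tr2 <- tr
  tr2$sentence_id <- "d2"
  f <- encode_forest(build_joined_forest(list(tr, tr2)))
  expect_identical(occurrence_signature(find_full_repeats(f)),
                   occurrence_signature(oracle_full_repeats(f)))
  expect_gt(length(find_full_repeats(f)), 0L)
})

test_that("child combinations enumerate all non-empty subsets deterministically", {
  expect_length(enumerate_child_combinations(letters[1:3]), 7L)
  expect_identical(enumerate_child_combinations(integer()), list())
  for (n in 1:8)
    expect_length(enumerate_child_combinations(seq_len(n)), 2^n - 1)
  expect_warning(res <- enumerate_child_combinations(1:9, max_children = 8),
                 "exceeds")
  expect_identical(res, list())
  expect_error(enumerate_child_combinations(1:9, 8, hard_error = TRUE),
               "exceeds")
  # deterministic order: by size, then position
  expect_identical(enumerate_child_combinations(c(10L, 20L))[[1]], 10L)
})

test_that("oracle hand-check: two identical 3-node trees give 6 repeated forms", {
  a <- make_tree("a", c("r", "l1", "l2"), c(0L, 1L, 1L))
  b <- make_tree("b", c("r", "l1", "l2"), c(0L, 1L, 1L))
  f <- encode_forest(build_joined_forest(list(a, b)))
  og <- oracle_partial_repeats(f)
  expect_length(og, 6L)
  expect_true(all(vapply(og, function(g) length(g$repeats), integer(1)) == 2L))
})

test_that("partial search equals the brute-force oracle on random forests", {
  for (seed in 1:150) {
    f <- random_forest(seed)
    expect_identical(
      occurrence_signature(find_partial_repeats(f, max_len = 5)),
      occurrence_signature(oracle_partial_repeats(f, max_len = 5)),
      label = sprintf("partial seed %d", seed))
    expect_identical(
      occurrence_signature(find_full_repeats(f)),
      occurrence_signature(oracle_full_repeats(f)),
      label = sprintf("full seed %d", seed))
  }
})

test_that("full-repeat forms are a subset of partial forms (length permitting)", {
  for (seed in 151:200) {
    f <- random_forest(seed)
    n <- nrow(f$nodes)
    full <- vapply(find_full_repeats(f), `[[`, character(1), "canonical")
    part <- vapply(find_partial_repeats(f, max_len = n), `[[`, character(1),
                   "canonical")
    expect_true(all(full %in% part), label = sprintf("seed %d", seed))
  }
})

test_that("planted repeats survive burial under an unrelated parent chain", {
  base <- make_tree("p1", c("root1", "ph", "pw"), c(0L, 1L, 2L))
  deep <- make_tree("p2", c("root2", "fill", "ph", "pw"), c(0L, 1L, 2L, 3L))
  f <- encode_forest(build_joined_forest(list(base, deep)))
  pg <- find_partial_repeats(f)
  two <- Filter(function(g) length(g$repeats[[1]]$members) == 2, pg)
  expect_length(two, 1L)
  expect_length(two[[1]]$repeats, 2L)
})

test_that("synonym nodes let similar phrases fall into one group", {
  # "a(b)" and "c(b)" are grouped once cos(a, c) > threshold
  t1 <- make_tree("y1", c("a", "b"), c(0L, 1L))
  t2 <- make_tree("y2", c("c", "b"), c(0L, 1L))
  f <- encode_forest(build_joined_forest(list(t1, t2)))
  sp <- embedding_space(rbind(a = c(1, 0), c = c(0.9, 0.43589), b = c(0, 1)))
  ext <- extend_forest(f, sp, 0.75)
  expect_identical(nrow(ext$provenance), 2L)  # a gains c, c gains a
  pg <- find_partial_repeats(ext$forest)
  two <- Filter(function(g) length(g$repeats[[1]]$members) == 2, pg)
  expect_gte(length(two), 1L)
  sents <- lapply(two, function(g)
    sort(vapply(g$repeats, `[[`, character(1), "sentence_id")))
  expect_true(any(vapply(sents, identical, logical(1), c("y1", "y2"))))
  # repeats are reported against original nodes only
  for (g in pg) for (r in g$repeats)
    expect_true(all(!f$nodes$is_added[match(r$members, f$nodes$id)]))
  # restored surfaces differ across the pair (said in other words)
  two <- restore_sequences(ext$forest, two)
  surf <- unlist(lapply(two, function(g) vapply(g$repeats, `[[`, character(1),
                                                "surface")))
  expect_gte(length(unique(surf)), 2L)
})

test_that("restored sequences follow token order", {
  # scrambled word order: members must come back in index order
  tr <- make_tree("o1", c("v", "n2", "n1"), c(0L, 1L, 1L),
                  forms = c("V", "N2", "N1"))
  tr2 <- make_tree("o2", c("n1", "v", "n2"), c(2L, 0L, 2L),
                   forms = c("N1", "V", "N2"))
  f <- encode_forest(build_joined_forest(list(tr, tr2)))
  pg <- restore_sequences(f, find_partial_repeats(f))
  three <- Filter(function(g) length(g$repeats[[1]]$members) == 3, pg)
  expect_length(three, 1L)
  surfaces <- vapply(three[[1]]$repeats, `[[`, character(1), "surface")
  expect_setequal(surfaces, c("V N2 N1", "N1 V N2"))
  for (r in three[[1]]$repeats)
    expect_identical(r$token_indices, sort(r$token_indices))
  # single-node repeat surface is that token's form
  ones <- Filter(function(g) length(g$repeats[[1]]$members) == 1, pg)
  for (g in ones)
    for (r in g$repeats) expect_identical(r$surface, toupper(r$lemmas))
})

test_that("group statistics count lengths and sizes", {
  empty <- group_statistics(structure(list(), class = "repeat_groups"))
  expect_length(empty$length_hist, 0L)
  tr <- lapply(1:3, function(i)
    make_tree(sprintf("g%d", i), c("aa", "bb"), c(0L, 1L)))
  f <- encode_forest(build_joined_forest(tr))
  pg <- find_partial_repeats(f)
  st <- group_statistics(pg)
  # forms: aa, bb, aa(bb) — each 3 times
  expect_identical(st$length_hist, c("1" = 2L, "2" = 1L))
  expect_identical(st$size_hist, c("3" = 3L))
  expect_identical(sum(st$size_hist), length(pg))
})

test_that("partial search output is deterministic and class vertices are wired", {
  f <- random_forest(77)
  g1 <- find_partial_repeats(f)
  g2 <- find_partial_repeats(f)
  expect_identical(occurrence_signature(g1), occurrence_signature(g2))
  expect_identical(vapply(g1, `[[`, character(1), "canonical"),
                   vapply(g2, `[[`, character(1), "canonical"))
  if (length(g1)) {
    ids <- unlist(lapply(g1, `[[`, "class_vertex_ids"))
    expect_true(all(ids < 0))
    expect_false(any(duplicated(ids)))
    g <- g1[[length(g1)]]
    for (k in seq_along(g$repeats)) {
      cv <- g$class_vertices[[k]]
      expect_identical(cv$parent_id, f$parent_of[g$repeats[[k]]$root])
      expect_true(all(cv$child_ids %in% g$repeats[[k]]$members))
    }
  }
})
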