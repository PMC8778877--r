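test_that("step bias matches the second-order walk rule", {
  cfg <- walk_config(p = 2, q = 3)
  expect_identical(step_bias(0L, cfg), 0.5)
  expect_identical(step_bias(1L, cfg), 1)
  expect_identical(step_bias(2L, cfg), 1 / 3)
  expect_identical(step_bias(0:2, walk_config(p = 1, q = 1)), rep(1, 3))
  expect_error(step_bias(3L, cfg), "must be in")
})

test_that("transition distribution normalizes biased, weighted neighbors", {
  star <- encode_forest(build_joined_forest(list(
    make_tree("s", c("c", "l1", "l2", "l3"), c(0L, 1L, 1L, 1L)))))
  center <- star$children_of[[star$virtual_root]]
  # cross_sentence = FALSE removes the virtual edge, so 3 leaves only
  pr <- transition_distribution(star, center, prev = NULL,
                                walk_config(cross_sentence = FALSE))
  expect_length(pr, 3)
  expect_equal(unname(pr), rep(1 / 3, 3))

  # path t - v - x with prev = t: biases 1/p and 1/q normalize to 0.6 / 0.4
  path <- encode_forest(build_joined_forest(list(
    make_tree("s", c("t", "v", "x"), c(0L, 1L, 2L)))))
  ids <- stats::setNames(path$nodes$id, path$nodes$lemma)
  pr <- transition_distribution(path, ids[["v"]], prev = ids[["t"]],
                                walk_config(p = 2, q = 3, cross_sentence = FALSE))
  expect_equal(unname(pr[as.character(ids[["t"]])]), 0.6)
  expect_equal(unname(pr[as.character(ids[["x"]])]), 0.4)

  # scaling all weights leaves the distribution unchanged
  tr <- make_tree("s", c("t", "v", "x"), c(0L, 1L, 2L))
  p1 <- build_joined_forest(list(tr))
  p2 <- build_joined_forest(list(tr), c(dep = 2.0))
  cfg <- walk_config(p = 2, q = 3, cross_sentence = FALSE)
  expect_equal(
    transition_distribution(encode_forest(p1), ids[["v"]], ids[["t"]], cfg),
    transition_distribution(encode_forest(p2), ids[["v"]], ids[["t"]], cfg))
})

test_that("walk generation is deterministic and respects the length cap", {
  f <- random_forest(11)
  cfg <- walk_config(walk_length = 1, seed = 3)
  w1 <- generate_walks(f, cfg)
  expect_true(all(lengths(w1) == 1L))
  eligible <- sum(!f$nodes$excluded & f$nodes$id != f$virtual_root)
  expect_length(w1, eligible * cfg$walks_per_start)

  cfg5 <- walk_config(seed = 9)
  expect_identical(generate_walks(f, cfg5), generate_walks(f, cfg5))
  expect_true(all(lengths(generate_walks(f, cfg5)) <= 5L))
})

test_that("stopword tokens are traversed but never emitted", {
  trees <- filter_stopwords(list(make_tree("s", c("r", "stop", "x"),
                                           c(0L, 1L, 2L))), "stop")
  f <- encode_forest(build_joined_forest(trees))
  w <- generate_walks(f, walk_config(seed = 2, walk_length = 3))
  expect_false("stop" %in% unlist(w))
  expect_true("x" %in% unlist(w))  # reachable only through the stopword
})

test_that("trainer covers the vocabulary and honors dimension and seed", {
  walks <- rep(list(c("a", "b", "c"), c("b", "c", "d")), 40)
  sp <- train_embeddings(walks, "cbow", dimension = 16, epochs = 2, seed = 4)
  expect_setequal(rownames(sp$vectors), c("a", "b", "c", "d"))
  expect_identical(ncol(sp$vectors), 16L)
  sp2 <- train_embeddings(walks, "cbow", dimension = 16, epochs = 2, seed = 4)
  expect_identical(sp$vectors, sp2$vectors)
  sp3 <- train_embeddings(walks, "skipgram", dimension = 16, epochs = 2, seed = 4)
  expect_false(identical(sp$vectors, sp3$vectors))
  expect_error(train_embeddings(list(), "cbow"), "empty")
})

test_that("cosine geometry is exact on constructed vectors", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  sp <- embedding_space(m)
  expect_equal(cosine_similarity(sp, "a", "a"), 1.0)
  expect_equal(cosine_similarity(sp, "a", "b"), 0.0)
  expect_equal(cosine_similarity(sp, "a", "c"), 0.70710678, tolerance = 1e-7)
  err <- tryCatch(cosine_similarity(sp, "a", "zz"), error = identity)
  expect_s3_class(err, "syntrep_oov_error")
})

test_that("nearest neighbors are sorted, self-free and thresholded", {
  sp <- space_with_cosines(c("w1", "w2", "w3"), "q", c(0.9, 0.8, 0.2))
  expect_identical(nrow(nearest_neighbors(sp, "q", threshold = 1.0)), 0L)
  nn <- nearest_neighbors(sp, "q", threshold = 0.75)
  expect_identical(nn$word, c("w1", "w2"))
  expect_true(all(diff(nn$similarity) <= 0))
  expect_false("q" %in% nn$word)
  # ties break lexicographically
  tie <- embedding_space(rbind(q = c(1, 0), zz = c(1, 0), aa = c(1, 0)))
  expect_identical(nearest_neighbors(tie, "q", 0.5)$word, c("aa", "zz"))
})

test_that("pretrained merge keeps trained vectors and is idempotent", {
  tr <- embedding_space(rbind(a = c(1, 0), b = c(0, 1)))
  pre <- embedding_space(rbind(b = c(5, 5), c = c(2, 2)),
                         provenance = c(b = "pretrained", c = "pretrained"))
  m <- merge_pretrained(tr, pre)
  expect_setequal(rownames(m$vectors), c("a", "b", "c"))
  expect_identical(m$vectors["b", ], c(0, 1))
  expect_identical(unname(m$provenance["c"]), "pretrained")
  expect_identical(merge_pretrained(m, pre)$vectors, m$vectors)
  bad <- embedding_space(matrix(1, 1, 3, dimnames = list("x", NULL)))
  expect_error(merge_pretrained(tr, bad), "dimension mismatch")
})

test_that("word2vec text format round-trips", {
  sp <- embedding_space(rbind(alpha = c(0.25, -1.5), beta = c(3, 4)))
  path <- tempfile(fileext = ".vec")
  write_word2vec(sp, path)
  back <- read_word2vec(path)
  expect_equal(back$vectors[rownames(sp$vectors), ], sp$vectors,
               tolerance = 1e-6)
  expect_true(all(back$provenance == "pretrained"))
})

test_that("empirical transitions converge to the analytic law", {
  # fixed 6-node tree; one long walk; conditional next-step frequencies
  f <- encode_forest(build_joined_forest(list(
    make_tree("s", c("r", "a", "b", "c", "d", "e"),
              c(0L, 1L, 1L, 2L, 2L, 3L)))))
  cfg <- walk_config(p = 2, q = 3, cross_sentence = TRUE)
  g <- syntrep:::forest_walk_graph(f, cfg)
  steps <- 2e4
  set.seed(99)
  cur <- g$starts[1]
  prev <- NULL
  trace <- matrix(NA_integer_, steps, 3)
  for (i in seq_len(steps)) {
    pr <- syntrep:::transition_probs(g, cur, prev, cfg)
    nxt <- pr$nb[sample.int(length(pr$nb), 1, prob = pr$prob)]
    trace[i, ] <- c(if (is.null(prev)) NA_integer_ else prev, cur, nxt)
    prev <- cur
    cur <- nxt
  }
  trace <- trace[!is.na(trace[, 1]), , drop = FALSE]
  key <- paste(trace[, 1], trace[, 2])
  max_tv <- 0
  for (k in unique(key)) {
    sub <- trace[key == k, , drop = FALSE]
    if (nrow(sub) < 500) next
    ana <- syntrep:::transition_probs(g, sub[1, 2], sub[1, 1], cfg)
    emp <- table(factor(sub[, 3], levels = ana$nb)) / nrow(sub)
    max_tv <- max(max_tv, sum(abs(as.numeric(emp) - ana$prob)) / 2)
  }
  expect_lt(max_tv, 0.05)
})

test_that("q > p keeps walks more local than p > q on a path graph", {
  chain <- make_tree("s", sprintf("w%02d", 1:40), c(0L, 1:39))
  f <- encode_forest(build_joined_forest(list(chain)))
  displacement <- function(p, q, seed) {
    w <- generate_walks(f, walk_config(p = p, q = q, walks_per_start = 3,
                                       walk_length = 8, seed = seed,
                                       cross_sentence = FALSE))
    pos <- function(lbl) as.integer(sub("w", "", lbl))
    mean(vapply(w, function(x) abs(pos(x[length(x)]) - pos(x[1])), numeric(1)))
  }
  expect_lte(displacement(2, 3, 17), displacement(1, 0.5, 17))
})
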