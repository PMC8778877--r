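# A restored group built directly, bypassing the mining stage.
fake_group <- function(id = "g0001", surfaces, lemma_seqs, upos_seqs = NULL,
                       feats_seqs = NULL, sentence_ids = NULL) {
  n <- length(surfaces)
  if (is.null(upos_seqs)) upos_seqs <- lapply(lemma_seqs, function(l)
    rep("NOUN", length(l)))
  if (is.null(feats_seqs)) feats_seqs <- lapply(lemma_seqs, function(l)
    rep("_", length(l)))
  if (is.null(sentence_ids)) sentence_ids <- sprintf("s%03d", seq_len(n))
  reps <- lapply(seq_len(n), function(i)
    list(root = i, members = i, sentence_id = sentence_ids[i],
         token_indices = seq_along(lemma_seqs[[i]]), surface = surfaces[i],
         lemmas = lemma_seqs[[i]], upos = upos_seqs[[i]],
         feats = feats_seqs[[i]]))
  structure(list(group_id = id, canonical = "x", repeats = reps,
                 surface_norm = normalize_text(surfaces)),
            class = "repeat_group")
}

test_that("vocabulary labeling matches single and multiword terms", {
  vocs <- list(load_vocabulary(c("aspirin"), "Medication"),
               load_vocabulary(c("diabetes mellitus"), "Disease"))
  g <- fake_group(surfaces = c("took Aspirin daily", "diabetes mellitus type"),
                  lemma_seqs = list(c("take", "aspirin", "daily"),
                                    c("diabetes", "mellitus", "type")))
  lab <- label_with_vocabulary(g, vocs)
  expect_setequal(lab$label_text, c("Medication", "Disease"))
  expect_setequal(lab$matched_term, c("aspirin", "diabetes mellitus"))
  expect_true(all(lab$source == "vocabulary"))
  expect_true(all(lab$relation == "none"))

  expect_identical(nrow(label_with_vocabulary(g, list())), 0L)
  # non-contiguous words do not match a multiword term
  g2 <- fake_group(surfaces = "diabetes severe mellitus",
                   lemma_seqs = list(c("diabetes", "severe", "mellitus")))
  expect_identical(nrow(label_with_vocabulary(g2, vocs[2])), 0L)
})

test_that("a term present in two vocabularies emits two labels", {
  vocs <- list(load_vocabulary("pain", "Disease"),
               load_vocabulary("pain", "Sign and symptom"))
  g <- fake_group(surfaces = "strong pain", lemma_seqs = list(c("strong", "pain")))
  lab <- label_with_vocabulary(g, vocs)
  expect_identical(nrow(lab), 2L)
  expect_setequal(lab$label_text, c("Disease", "Sign and symptom"))
})

test_that("timestamp detection covers years, numeric dates and day-month", {
  yes <- list(
    fake_group(surfaces = "identified in 2009",
               lemma_seqs = list(c("identify", "in", "2009"))),
    fake_group(surfaces = "on 19 July admitted",
               lemma_seqs = list(c("on", "19", "july", "admit"))),
    fake_group(surfaces = "seen 03.12.2014",
               lemma_seqs = list(c("see", "03.12.2014"))))
  for (g in yes) expect_true(detect_timestamp(g))
  no <- fake_group(surfaces = "chronic disease history",
                   lemma_seqs = list(c("chronic", "disease", "history")))
  expect_false(detect_timestamp(no))
  # custom patterns override the defaults
  expect_false(detect_timestamp(yes[[1]], date_patterns = "XXXX"))
})

test_that("event detection uses passive voice or the verb lexicon", {
  passive <- fake_group(surfaces = "was hospitalized urgently",
                        lemma_seqs = list(c("be", "hospitalizzzz", "urgently")),
                        upos_seqs = list(c("AUX", "VERB", "ADV")),
                        feats_seqs = list(c("_", "Voice=Pass", "_")))
  expect_true(detect_event(passive))
  noverb <- fake_group(surfaces = "severe pain",
                       lemma_seqs = list(c("severe", "pain")))
  expect_false(detect_event(noverb))
  active_lex <- fake_group(surfaces = "identified in 2009",
                           lemma_seqs = list(c("identify", "in", "2009")),
                           upos_seqs = list(c("VERB", "ADP", "NUM")))
  expect_true(detect_event(active_lex))
  active_other <- fake_group(surfaces = "walks daily",
                             lemma_seqs = list(c("walk", "daily")),
                             upos_seqs = list(c("VERB", "ADV")))
  expect_false(detect_event(active_other))
})

test_that("candidate phrases are k-permutations of distinct noun/adj lemmas", {
  g <- fake_group(surfaces = "acute pain", lemma_seqs = list(c("acute", "pain")),
                  upos_seqs = list(c("ADJ", "NOUN")))
  ph <- candidate_phrases(g)
  expect_setequal(ph, c("acute", "pain", "acute pain", "pain acute"))

  verbs_only <- fake_group(surfaces = "was discharged",
                           lemma_seqs = list(c("be", "discharge")),
                           upos_seqs = list(c("AUX", "VERB")))
  expect_identical(candidate_phrases(verbs_only), character())

  # |phrases| = sum over k of P(m, k), checked for m = 1..4
  for (m in 1:4) {
    lemmas <- letters[seq_len(m)]
    g <- fake_group(surfaces = paste(lemmas, collapse = " "),
                    lemma_seqs = list(lemmas))
    expected <- sum(vapply(seq_len(min(3, m)), function(k)
      prod((m - k + 1):m), numeric(1)))
    expect_length(candidate_phrases(g, max_words = 3), expected)
  }
})

test_that("linking embeddings train on the KB graph alone and are reproducible", {
  kb <- generate_toy_kb()$kb
  cfg <- walk_config(p = 1, q = 2, walks_per_start = 3, walk_length = 5, seed = 6)
  expect_identical(cfg$p, 1)
  expect_identical(cfg$q, 2)
  expect_identical(cfg$walks_per_start, 3L)
  expect_identical(cfg$walk_length, 5L)
  sp1 <- train_kb_embeddings(kb, NULL, cfg, dimension = 24, epochs = 3)
  sp2 <- train_kb_embeddings(kb, NULL, cfg, dimension = 24, epochs = 3)
  expect_identical(sp1$vectors, sp2$vectors)
  expect_true("electrocardiogram" %in% rownames(sp1$vectors))
  expect_true("ekg" %in% rownames(sp1$vectors))
  empty_kb <- build_kb(list())
  expect_error(train_kb_embeddings(empty_kb, NULL, cfg), "empty union graph")
})

test_that("the union graph joins forest lemmas with KB names", {
  kb <- generate_toy_kb()$kb
  trees <- list(make_tree("u1", c("seen", "pain"), c(0L, 1L)))
  f <- encode_forest(build_joined_forest(trees))
  sp <- train_kb_embeddings(kb, f, walk_config(p = 1, q = 2, walks_per_start = 3,
                                               walk_length = 5, seed = 2),
                            dimension = 24, epochs = 3)
  expect_true(all(c("seen", "pain", "negative emotion") %in% rownames(sp$vectors)))
})

test_that("disambiguation picks the highest-cosine category", {
  sp <- space_with_cosines(c("negative emotion", "livelihood"), "pain",
                           c(0.75, 0.31))
  cands <- data.frame(qid = c("Q300", "Q301"),
                      category_name = c("negative emotion", "livelihood"),
                      stringsAsFactors = FALSE)
  pick <- disambiguate("pain", cands, sp)
  expect_identical(pick$qid, "Q300")
  expect_identical(pick$category_name, "negative emotion")
  expect_equal(pick$score, 0.75, tolerance = 1e-6)
  expect_false(pick$low_confidence)

  single <- disambiguate("pain", cands[1, ], sp)
  expect_identical(single$qid, "Q300")

  oov <- disambiguate("pain", data.frame(qid = c("Q9", "Q8"),
                                         category_name = c("zz", "yy")), sp)
  expect_identical(oov$qid, "Q8")  # first by qid order
  expect_true(oov$low_confidence)
  expect_error(disambiguate("pain", cands[0, ], sp), "empty")
})

test_that("KB labeling resolves matches, ambiguity and relation precedence", {
  kb <- generate_toy_kb()$kb
  g <- fake_group(surfaces = "routine ekg today",
                  lemma_seqs = list(c("routine", "ekg", "today")),
                  upos_seqs = list(c("ADJ", "NOUN", "ADV")))
  lab <- label_with_kb(g, kb, NULL)
  expect_identical(lab$label_text, "medical test type")
  expect_identical(lab$source, "wikidata")
  expect_identical(lab$relation, "instance_of")
  expect_identical(lab$entity_qid, "Q100")
  expect_identical(lab$matched_term, "ekg")

  none <- fake_group(surfaces = "nothing here",
                     lemma_seqs = list(c("nothing", "here")))
  expect_identical(nrow(label_with_kb(none, kb, NULL)), 0L)

  amb <- fake_group(surfaces = "pain", lemma_seqs = list("pain"))
  sp <- space_with_cosines(c("negative emotion", "livelihood"), "pain",
                           c(0.75, 0.31))
  lab2 <- label_with_kb(amb, kb, sp)
  expect_identical(lab2$label_text, "negative emotion")
  expect_identical(lab2$entity_qid, "Q300")
})

test_that("annotation applies all sources and reports conserved counts", {
  toy <- generate_toy_kb()
  groups <- structure(list(
    fake_group("g1", "routine ekg", list(c("routine", "ekg")),
               list(c("ADJ", "NOUN")), sentence_ids = "sA"),
    fake_group("g2", "identified in 2009", list(c("identify", "in", "2009")),
               list(c("VERB", "ADP", "NUM")), sentence_ids = "sB"),
    fake_group("g3", "plain words", list(c("plain", "word")),
               sentence_ids = "sC")), class = "repeat_groups")
  ann <- annotate_groups(groups, toy$kb, toy$vocabularies, NULL,
                         sentence_ids = c("sA", "sB", "sC", "sD"))
  expect_identical(sum(ann$report$source_counts), nrow(ann$labels))
  expect_identical(ann$report$sentences_total, 4L)
  expect_identical(ann$report$sentences_covered, 2L)  # sA (kb), sB (ts+event)
  expect_equal(ann$report$coverage_fraction, 0.5)
  expect_true(all(c("timestamp", "event", "wikidata") %in% names(
    ann$report$source_counts)))

  # label multiset is invariant under group order
  ann2 <- annotate_groups(structure(rev(unclass(groups)),
                                    class = "repeat_groups"),
                          toy$kb, toy$vocabularies, NULL,
                          sentence_ids = c("sA", "sB", "sC", "sD"))
  expect_identical(ann2$report$sentences_covered, 2L)
  sig <- function(l) sort(paste(l$group_id, l$label_text, l$source))
  expect_identical(sig(ann$labels), sig(ann2$labels))

  # adding a vocabulary term can only increase coverage
  vocs3 <- c(toy$vocabularies, list(load_vocabulary("plain", "Disease")))
  ann3 <- annotate_groups(groups, toy$kb, vocs3, NULL,
                          sentence_ids = c("sA", "sB", "sC", "sD"))
  expect_gte(ann3$report$sentences_covered, ann$report$sentences_covered)
  expect_identical(ann3$report$sentences_covered, 3L)

  # all groups label-free -> zero coverage
  bare <- structure(list(groups[[3]]), class = "repeat_groups")
  ann4 <- annotate_groups(bare, NULL, list(), NULL, sentence_ids = "sC")
  expect_identical(ann4$report$sentences_covered, 0L)
  expect_identical(ann4$report$coverage_fraction, 0)
})
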