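# Build a sentence_tree from parallel vectors (heads are 1-based, 0 = root).
make_tree <- function(sentence_id, lemmas, heads, upos = NULL, feats = NULL,
                      forms = NULL, deprel = NULL) {
  n <- length(lemmas)
  if (is.null(upos)) upos <- rep("NOUN", n)
  if (is.null(feats)) feats <- rep("_", n)
  if (is.null(forms)) forms <- lemmas
  if (is.null(deprel)) deprel <- ifelse(heads == 0, "root", "dep")
  lines <- sprintf("%d\t%s\t%s\t%s\t_\t%s\t%d\t%s\t_\t_",
                   seq_len(n), forms, lemmas, upos, feats, heads, deprel)
  read_conllu(paste0("# sent_id = ", sentence_id, "\n",
                     paste(lines, collapse = "\n"), "\n"))[[1]]
}

# Random forest of random recursive trees over a small lemma alphabet.
# Trees are constructed directly (construction guarantees validity); the
# CoNLL-U parser has its own tests.
random_trees <- function(seed, max_trees = 8, max_nodes = 10, alphabet = 6) {
  set.seed(seed)
  n_trees <- sample.int(max_trees, 1)
  lapply(seq_len(n_trees), function(t) {
    n <- sample.int(max_nodes, 1)
    heads <- c(0L, if (n > 1) vapply(2:n, function(i)
      sample.int(i - 1L, 1), integer(1)))
    lemmas <- sample(letters[seq_len(alphabet)], n, replace = TRUE)
    tokens <- data.frame(index = seq_len(n), form = lemmas, lemma = lemmas,
                         upos = "NOUN", feats = "_", head = heads,
                         deprel = ifelse(heads == 0, "root", "dep"),
                         excluded = FALSE, stringsAsFactors = FALSE)
    structure(list(sentence_id = sprintf("t%d", t), tokens = tokens),
              class = "sentence_tree")
  })
}

random_forest <- function(seed, ...) {
  encode_forest(build_joined_forest(random_trees(seed, ...)))
}

# Group lists are compared by their occurrence structure: for each group the
# sorted set of (sentence, member-id) occurrence keys. In forests without
# synonym nodes this determines the canonical form sets exactly.
occurrence_signature <- function(groups) {
  sort(vapply(groups, function(g) {
    keys <- vapply(g$repeats, function(r)
      paste0(r$sentence_id, ":", paste(sort(r$members), collapse = ",")),
      character(1))
    paste(sort(keys), collapse = "|")
  }, character(1)))
}

# Reconstruction of the extra-child example: two clinical sentences that
# share only the phrase "infarction myocardial"; the second carries an extra
# word below it, so no full subtree repeats but the 2-word partial does.
extra_child_trees <- function() {
  list(
    make_tree("ec_a", c("patient", "suffer", "infarction", "myocardial"),
              heads = c(2L, 0L, 2L, 3L),
              upos = c("NOUN", "VERB", "NOUN", "ADJ")),
    make_tree("ec_b", c("confirm", "infarction", "myocardial", "second"),
              heads = c(0L, 1L, 2L, 3L),
              upos = c("VERB", "NOUN", "ADJ", "ADJ")))
}

# Reconstruction of the depth-shift example: the 4-word phrase "assigned a
# diagnosis diabetes mellitus" roots at height 3 in one sentence and height 4
# in the other, so single-height full matching misses it.
depth_shift_trees <- function() {
  list(
    make_tree("ds_a", c("therapist", "assigned", "diagnosis", "diabetes", "mellitus"),
              heads = c(2L, 0L, 2L, 3L, 4L),
              upos = c("NOUN", "VERB", "NOUN", "NOUN", "ADJ")),
    make_tree("ds_b", c("cardiologist", "assigned", "diagnosis", "diabetes",
                        "mellitus", "ii"),
              heads = c(2L, 0L, 2L, 3L, 4L, 5L),
              upos = c("NOUN", "VERB", "NOUN", "NOUN", "ADJ", "NUM")))
}

# An embedding space with prescribed pairwise cosines, built from 2-D vectors.
space_with_cosines <- function(words, base, cosines) {
  stopifnot(length(words) == length(cosines))
  vecs <- rbind(c(1, 0),
                t(vapply(cosines, function(cs) c(cs, sqrt(1 - cs^2)), numeric(2))))
  rownames(vecs) <- c(base, words)
  embedding_space(vecs)
}
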