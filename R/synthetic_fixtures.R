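#' Planted repeat template
#'
#' Describes one dependency-tree fragment the corpus generator plants a
#' fixed number of times. Templates are the machine-readable ground truth
#' that mining and labeling results are checked against.
#'
#' @param lemmas Character vector of template lemmas (language-neutral
#'   pseudo-lemmas work fine; the pipeline never needs real words).
#' @param shape Integer parent vector, one entry per lemma, `0` marking the
#'   template root (parents are template-internal positions).
#' @param count How many times the template occurs in the corpus (use at
#'   least 2 for templates meant to be found).
#' @param jitter Maximum number of extra unrelated ancestor nodes inserted
#'   between the sentence root and the template root, re-creating the
#'   depth-shift that defeats single-height matching.
#' @param upos POS tags per lemma (default all `"NOUN"`).
#' @param label_category `NA`, one of the four vocabulary categories, or
#'   `"wikidata"`: the generator then guarantees matching label resources
#'   for `label_term`.
#' @param label_term The lemma (or contiguous lemma phrase) registered in
#'   the vocabulary/KB; defaults to the first lemma.
#' @param feats Per-lemma morphological feature strings (default `"_"`).
#' @return A `fixture_template` list.
#' @export
fixture_template <- function(lemmas, shape = NULL, count = 2, jitter = 0,
                             upos = NULL, label_category = NA_character_,
                             label_term = NULL, feats = NULL) {
  k <- length(lemmas)
  if (is.null(shape)) shape <- c(0L, rep(1L, k - 1L))  # flat: root + leaves
  if (is.null(upos)) upos <- rep("NOUN", k)
  if (is.null(feats)) feats <- rep("_", k)
  stopifnot(length(shape) == k, length(upos) == k, sum(shape == 0) == 1)
  if (is.null(label_term)) label_term <- lemmas[[1]]
  structure(list(lemmas = lemmas, shape = as.integer(shape), count = as.integer(count),
                 jitter = as.integer(jitter), upos = upos,
                 label_category = label_category, label_term = label_term,
                 feats = feats), class = "fixture_template")
}

#' Fixture corpus specification
#'
#' Declares a synthetic parsed corpus: noise vocabulary sizes, the planted
#' repeat templates, planted synonym pairs (each realized by swapping the
#' two lemmas across occurrences of an otherwise identical context
#' template), free date tokens, passive-voice roots, and a seed. The same
#' seed always yields byte-identical output.
#'
#' @param n_sentences Number of sentences.
#' @param templates List of [fixture_template()] objects.
#' @param synonym_pairs List of 2-element character vectors; each pair gets
#'   its own 4-word context template planted `synonym_occurrences` times
#'   with the slot alternating between the two lemmas.
#' @param synonym_occurrences Occurrences per synonym context template
#'   (default 12).
#' @param n_content,n_function Sizes of the noise noun and verb lemma
#'   pools.
#' @param date_rate Probability that a sentence gets a free-standing
#'   four-digit year token.
#' @param passive_rate Probability that a sentence root verb carries
#'   `Voice=Pass`.
#' @param max_noise Maximum extra noise tokens per sentence.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_sentences = 100, templates = list(),
                         synonym_pairs = list(), synonym_occurrences = 12,
                         n_content = 40, n_function = 12, date_rate = 0.1,
                         passive_rate = 0.1, max_noise = 3, seed = 1L) {
  stopifnot(n_sentences >= 0, n_content >= 1, n_function >= 1,
            date_rate >= 0, date_rate <= 1, passive_rate >= 0, passive_rate <= 1)
  structure(list(n_sentences = as.integer(n_sentences), templates = templates,
                 synonym_pairs = synonym_pairs,
                 synonym_occurrences = as.integer(synonym_occurrences),
                 n_content = as.integer(n_content),
                 n_function = as.integer(n_function), date_rate = date_rate,
                 passive_rate = passive_rate, max_noise = as.integer(max_noise),
                 seed = as.integer(seed)), class = "fixture_spec")
}

#' Generate a synthetic CoNLL-U corpus with ground truth
#'
#' Builds `n_sentences` dependency trees: each sentence has a verb root,
#' optional planted template instances (attached under up to `jitter`
#' extra ancestors), noise tokens, optional date tokens and passive roots,
#' and a random token order (free word order). Noise lemma pools are
#' disjoint from template lemmas, so each template occurs exactly its
#' stated count. Synonym pairs are realized by swapping the pair lemmas
#' across occurrences of a dedicated context template.
#'
#' @param spec A [fixture_spec()].
#' @return List with `conllu` (text), `truth` (occurrences per template,
#'   labelable sentences, expected coverage fraction, synonym pairs, label
#'   resources), and `spec`.
#' @export
generate_corpus <- function(spec) {
  templates <- spec$templates
  # one context template per synonym pair: the slot sits under the first
  # context word with one sibling and three children, so both pair members
  # see an identical, information-rich neighborhood
  for (i in seq_along(spec$synonym_pairs)) {
    pair <- spec$synonym_pairs[[i]]
    ctx <- sprintf("sctx%02d%s", i, letters[1:5])
    templates[[length(templates) + 1L]] <- fixture_template(
      lemmas = c(ctx[1], "<slot>", ctx[2], ctx[3], ctx[4], ctx[5]),
      shape = c(0L, 1L, 1L, 2L, 2L, 2L), count = spec$synonym_occurrences,
      upos = c("VERB", "NOUN", "NOUN", "NOUN", "ADJ", "NOUN"))
    attr(templates[[length(templates)]], "slot_pair") <- pair
  }
  for (tpl in templates)
    if (length(tpl$lemmas) + tpl$jitter + 1L > 60L)
      stop("template longer than the sentence budget")
  total_occ <- sum(vapply(templates, `[[`, integer(1), "count"))
  if (spec$n_sentences == 0) {
    if (total_occ > 0) stop("templates planted but n_sentences is 0")
    return(list(conllu = "", truth = empty_truth(), spec = spec))
  }
  if (total_occ > 0 && spec$n_sentences < 1)
    stop("not enough sentences for the planted occurrences")
  with_seed(spec$seed, generate_corpus_impl(spec, templates))
}

empty_truth <- function() {
  list(occurrences = list(), labelable_sentences = character(), coverage = 0,
       synonym_pairs = list(), vocab_terms = list(), kb_terms = character(),
       sentence_ids = character())
}

generate_corpus_impl <- function(spec, templates) {
  nouns <- sprintf("nzz%03d", seq_len(spec$n_content))
  verbs <- sprintf("vzz%03d", seq_len(spec$n_function))
  sids <- sprintf("s%04d", seq_len(spec$n_sentences))
  # assign template occurrences to sentences, spreading them out
  assign <- vector("list", spec$n_sentences)
  slot_choice <- list()
  cursor <- sample.int(spec$n_sentences)
  pos <- 0L
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    for (occ in seq_len(tpl$count)) {
      pos <- pos + 1L
      if (pos > length(cursor)) {
        cursor <- c(cursor, sample.int(spec$n_sentences))
      }
      s <- cursor[pos]
      assign[[s]] <- c(assign[[s]], list(list(ti = ti, occ = occ)))
    }
  }
  occurrences <- lapply(seq_along(templates), function(i) list())
  sent_text <- character(spec$n_sentences)
  for (s in seq_len(spec$n_sentences)) {
    # build nodes in construction order: parent, lemma, upos, feats, deprel
    lemma <- sample(verbs, 1)
    feats <- if (stats::runif(1) < spec$passive_rate) "Voice=Pass" else "_"
    nodes <- list(list(parent = 0L, lemma = lemma, upos = "VERB", feats = feats,
                       deprel = "root", tpl = NA_integer_, tpos = NA_integer_))
    for (inst in assign[[s]]) {
      tpl <- templates[[inst$ti]]
      lem <- tpl$lemmas
      pair <- attr(tpl, "slot_pair")
      if (!is.null(pair))
        lem[lem == "<slot>"] <- pair[(inst$occ %% 2L) + 1L]
      # jitter chain of unrelated ancestors between sentence root and template
      anchor <- 1L
      d <- if (tpl$jitter > 0) sample.int(tpl$jitter + 1L, 1L) - 1L else 0L
      for (j in seq_len(d)) {
        nodes[[length(nodes) + 1L]] <- list(parent = anchor,
                                            lemma = sample(nouns, 1),
                                            upos = "NOUN", feats = "_",
                                            deprel = "dep", tpl = NA_integer_,
                                            tpos = NA_integer_)
        anchor <- length(nodes)
      }
      base <- length(nodes)
      for (k in seq_along(lem)) {
        par <- if (tpl$shape[k] == 0L) anchor else base + tpl$shape[k]
        nodes[[length(nodes) + 1L]] <- list(parent = par, lemma = lem[k],
                                            upos = tpl$upos[k],
                                            feats = tpl$feats[k],
                                            deprel = if (tpl$shape[k] == 0L)
                                              "obj" else "nmod",
                                            tpl = inst$ti, tpos = k)
      }
    }
    n_noise <- sample.int(spec$max_noise + 1L, 1L) - 1L
    for (j in seq_len(n_noise)) {
      nodes[[length(nodes) + 1L]] <- list(parent = sample.int(length(nodes), 1L),
                                          lemma = sample(nouns, 1),
                                          upos = "NOUN", feats = "_",
                                          deprel = "dep", tpl = NA_integer_,
                                          tpos = NA_integer_)
    }
    if (stats::runif(1) < spec$date_rate) {
      year <- as.character(sample(1990:2020, 1))
      nodes[[length(nodes) + 1L]] <- list(parent = 1L, lemma = year,
                                          upos = "NUM", feats = "_",
                                          deprel = "nummod", tpl = NA_integer_,
                                          tpos = NA_integer_)
    }
    # free word order: random permutation of construction order
    n <- length(nodes)
    perm <- sample.int(n)             # perm[i] = final index of node i
    inv <- integer(n)
    inv[perm] <- seq_len(n)
    lines <- character(n)
    occ_idx <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      nd <- nodes[[i]]
      head <- if (nd$parent == 0L) 0L else perm[nd$parent]
      lines[perm[i]] <- sprintf("%d\t%s\t%s\t%s\t_\t%s\t%d\t%s\t_\t_",
                                perm[i], nd$lemma, nd$lemma, nd$upos, nd$feats,
                                head, nd$deprel)
      if (!is.na(nd$tpl)) {
        key <- as.character(nd$tpl)
        occ_idx[[key]] <- c(occ_idx[[key]], perm[i])
      }
    }
    for (inst in assign[[s]]) {
      key <- as.character(inst$ti)
      # indices for this sentence's instances of template ti, in plant order
      all_idx <- occ_idx[[key]]
      k <- length(templates[[inst$ti]]$lemmas)
      taken <- sum(vapply(occurrences[[inst$ti]], function(o)
        identical(o$sentence_id, sids[s]), logical(1)))
      idx <- sort(all_idx[(taken * k + 1):((taken + 1) * k)])
      occurrences[[inst$ti]][[length(occurrences[[inst$ti]]) + 1L]] <-
        list(sentence_id = sids[s], token_indices = idx)
    }
    sent_text[s] <- paste0("# sent_id = ", sids[s], "\n",
                           paste(lines, collapse = "\n"), "\n\n")
  }
  # ground truth label resources and coverage
  vocab_cats <- c("Disease", "Sign and symptom", "Medication",
                  "Physician specialization")
  vocab_terms <- stats::setNames(vector("list", 4), vocab_cats)
  kb_terms <- character()
  labelable <- character()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    lc <- tpl$label_category
    has_date <- any(grepl("^(19|20)[0-9]{2}$", tpl$lemmas))
    has_event <- any(tpl$upos == "VERB" &
                       (grepl("Voice=Pass", tpl$feats, fixed = TRUE) |
                          tpl$lemmas %in% default_event_lexicon()))
    labeled <- (!is.na(lc)) || has_date || has_event
    if (!is.na(lc)) {
      if (lc == "wikidata") kb_terms <- c(kb_terms, tpl$label_term)
      else vocab_terms[[lc]] <- c(vocab_terms[[lc]], tpl$label_term)
    }
    if (labeled)
      labelable <- union(labelable, vapply(occurrences[[ti]], `[[`,
                                           character(1), "sentence_id"))
  }
  truth <- list(
    occurrences = lapply(seq_along(templates), function(ti)
      list(lemmas = templates[[ti]]$lemmas,
           slot_pair = attr(templates[[ti]], "slot_pair"),
           occurrences = occurrences[[ti]])),
    labelable_sentences = sort(labelable),
    coverage = length(labelable) / spec$n_sentences,
    synonym_pairs = spec$synonym_pairs,
    vocab_terms = vocab_terms, kb_terms = unique(kb_terms),
    sentence_ids = sids)
  list(conllu = paste(sent_text, collapse = ""), truth = truth, spec = spec)
}

#' Label resources matching a generated corpus
#'
#' Builds the domain vocabularies and a small knowledge base covering
#' exactly the labelable terms a [generate_corpus()] ground truth declares,
#' so an end-to-end run can be checked against the planted coverage. Every
#' KB term gets an entity whose `instance_of` target is a named category
#' entity `"<term> category"`.
#'
#' @param corpus The list returned by [generate_corpus()].
#' @return List with `vocabularies` (list of `domain_vocabulary`) and `kb`
#'   (a `medical_kb`, `NULL` when no KB terms were planted).
#' @export
fixture_resources <- function(corpus) {
  truth <- corpus$truth
  vocabularies <- list()
  for (cat in names(truth$vocab_terms)) {
    terms <- truth$vocab_terms[[cat]]
    if (length(terms))
      vocabularies[[length(vocabularies) + 1L]] <- load_vocabulary(terms, cat)
  }
  kb <- NULL
  if (length(truth$kb_terms)) {
    records <- list()
    for (i in seq_along(truth$kb_terms)) {
      term <- truth$kb_terms[i]
      qe <- sprintf("Q%d", 1000 + i)
      qc <- sprintf("Q%d", 2000 + i)
      records[[length(records) + 1L]] <- kb_record(qe, term, instance_of = qc,
                                                   properties = "P486")
      records[[length(records) + 1L]] <- kb_record(qc, paste(term, "category"))
    }
    kb <- build_kb(records, language_code = "xx")
  }
  list(vocabularies = vocabularies, kb = kb)
}

#' Demonstration corpus specification
#'
#' The fixture used by the package's end-to-end examples and checks: a
#' corpus with four labelable planted constructions — a disease phrase
#' (vocabulary route), a medical-test phrase (knowledge-base route), an
#' "identified in <year>" construction (timestamp + event route), a
#' passive-voice discharge construction (event route) — plus two planted
#' synonym pairs. Every labelable template carries enough fixed context
#' words that its embedding is well determined, so labels do not leak into
#' noise sentences and the report's coverage can be checked exactly
#' against the ground truth.
#'
#' @param n_sentences Corpus size (default 500).
#' @param seed Integer seed.
#' @return A [fixture_spec()].
#' @export
demo_corpus_spec <- function(n_sentences = 500, seed = 1L) {
  # planted densities are per-500-sentences; scaling keeps small corpora sane
  sc <- function(per500) max(2L, as.integer(round(per500 * n_sentences / 500)))
  templates <- list(
    fixture_template(c("ctxd1", "infarction", "myocardial", "ctxd2", "ctxd3"),
                     shape = c(0L, 1L, 2L, 1L, 2L), count = sc(16), jitter = 2,
                     upos = c("VERB", "NOUN", "ADJ", "NOUN", "NOUN"),
                     label_category = "Disease", label_term = "infarction"),
    fixture_template(c("ctxk1", "ekgterm", "ctxk2", "ctxk3", "ctxk4"),
                     shape = c(0L, 1L, 1L, 2L, 2L), count = sc(16),
                     upos = c("VERB", "NOUN", "NOUN", "ADJ", "NOUN"),
                     label_category = "wikidata", label_term = "ekgterm"),
    fixture_template(c("identify", "2009", "ctxt1", "ctxt2", "ctxt3"),
                     shape = c(0L, 1L, 1L, 1L, 3L), count = sc(14),
                     upos = c("VERB", "NUM", "NOUN", "NOUN", "ADJ")),
    fixture_template(c("discharged", "ward", "ctxp1", "ctxp2", "ctxp3"),
                     shape = c(0L, 1L, 1L, 2L, 2L), count = sc(14),
                     upos = c("VERB", "NOUN", "NOUN", "ADJ", "NOUN"),
                     feats = c("Voice=Pass", "_", "_", "_", "_")))
  fixture_spec(n_sentences = n_sentences, templates = templates,
               synonym_pairs = list(c("synaa", "synab"), c("synba", "synbb")),
               synonym_occurrences = sc(12), n_content = 50, n_function = 12,
               date_rate = 0, passive_rate = 0, seed = seed)
}

#' Generate the toy knowledge base
#'
#' A small, fully deterministic KB exercising every lookup and resolution
#' path: an "electrocardiogram"-shaped entity with two aliases and all
#' three inheritance relations; two entities sharing the alias "pain" with
#' distinct instance-of categories (the ambiguity the disambiguation rule
#' settles); an entity whose instance-of target exists but has no
#' translated name (fallback chain); plus four tiny domain vocabularies.
#'
#' @param seed Unused placeholder for API symmetry; the structure is fixed.
#' @return List with `records`, `kb` (built store), and `vocabularies`.
#' @export
generate_toy_kb <- function(seed = 1L) {
  records <- list(
    kb_record("Q100", "electrocardiogram", aliases = c("EKG", "ECG"),
              instance_of = "Q200", subclass_of = "Q201", part_of = "Q202",
              properties = "P486"),
    kb_record("Q200", "medical test type"),
    kb_record("Q201", "medical test"),
    kb_record("Q202", "electrophysiology"),
    kb_record("Q300", "pain", instance_of = "Q302", properties = "P486"),
    kb_record("Q301", "nociception", aliases = "pain", instance_of = "Q303",
              properties = "P486"),
    kb_record("Q302", "negative emotion"),
    kb_record("Q303", "livelihood"),
    # fallback chain: instance-of target present but untranslated
    kb_record("Q400", "troponin test", instance_of = "Q401",
              subclass_of = "Q402", part_of = "Q403", properties = "P486"),
    kb_record("Q401", NA_character_),
    kb_record("Q402", "laboratory test"),
    kb_record("Q403", "blood analysis"))
  vocabularies <- list(
    load_vocabulary(c("infarction", "diabetes mellitus", "stroke"), "Disease"),
    load_vocabulary(c("pain", "nausea", "dizziness"), "Sign and symptom"),
    load_vocabulary(c("aspirin", "furosemide"), "Medication"),
    load_vocabulary(c("cardiologist", "paramedic"), "Physician specialization"))
  list(records = records, kb = build_kb(records, language_code = "en"),
       vocabularies = vocabularies)
}
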