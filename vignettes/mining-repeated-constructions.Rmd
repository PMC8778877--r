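---
title: "Mining and labeling repeated constructions in dependency-parsed clinical text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and labeling repeated constructions in dependency-parsed clinical text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntrep)
```

## The problem

Clinical free text is repetitive: admission notes restate the same
constructions ("assigned a diagnosis X", "identified in YEAR", "was
discharged to ...") with small variations in wording, word order and
position inside the sentence. In languages without mature medical
terminologies there is no labeled data to train extraction models on, and
hand-annotation is expensive. `syntrep` implements an unsupervised route:
group recurring syntactic fragments across a dependency-parsed corpus, then
label whole groups at once with domain vocabularies, simple date/voice
heuristics, and a medical slice of a Wikidata-style knowledge base. A
sentence is "covered" when it contains at least one repeat belonging to a
labeled group.

Parsing itself is out of scope: input is CoNLL-U produced by any
morphological/syntactic parser. All matching happens on the parser's
lemmas after a single normalization (NFC, case folding, whitespace
collapsing, stripping punctuation that hugs a token); the package never
re-lemmatizes.

## From sentences to one tree

Every sentence tree's root is attached to one artificial *virtual root*,
giving a single joined forest. Two things are gained: random walks can
cross sentence boundaries (the corpus is one training graph), and repeat
search runs once over the whole corpus instead of per pair of sentences.
Edges carry their dependency relation and a numeric weight from a
user-editable table. The weight default is 1.0 for every relation: the
mechanism of relation-dependent weights is preserved, but the neutral
default keeps results reproducible and makes no unsupported claims about
which relations matter. Virtual-root edges are walkable (configurable off
via `cross_sentence`) but can never be part of a repeat — repeat roots are
always real tokens.

Stopwords are *flagged*, not deleted: flagged tokens are excluded from walk
emission and from the embedding vocabulary, but stay in the trees so that
subtree shapes seen by the repeat search are unchanged. The original
description removes stop words "before training" without saying what the
repeat search sees; flagging keeps both readings available and we default
to the conservative one (structure intact).

## Walk-based embeddings

Similarity between words is cosine similarity between embeddings trained on
biased second-order random walks over the joined forest. A step from node
`v`, having arrived from `t`, weighs each neighbor `x` by
`bias(d) * weight(v, x)` where `d` is the shortest-path distance from `t`
to `x`: `1/p` for `d = 0`, `1` for `d = 1`, `1/q` for `d = 2`. The
defaults are `p = 2`, `q = 3`, five walks from every eligible node, at
most five emitted words per walk, used non-normalized exactly as given.
With `q > p` the walk is biased toward the local neighborhood, which fits
trees: a word's syntactic dependents and head carry more meaning for it
than distant corpus context. "Walks per root" is read as walks from
*every* eligible node (the standard sampling strategy, and walks are
generated "for each node"), not only from sentence roots.

The walk corpus feeds a deterministic single-threaded word2vec trainer
(negative sampling, implemented in C++ inside the package): CBOW for the
grouping embeddings, skip-gram for the linking embeddings used in
knowledge-base disambiguation. The exact optimizer is not prescribed
anywhere; any standard CBOW/skip-gram trainer satisfies the contract we
document: fixed seed + single worker + fixed epochs gives identical output
on one platform, and stable neighbor *ranks* across platforms (last-ulp
float drift must not reorder neighbors). Defaults the source text does not
state, chosen once: `dimension = 100`, `window = 5`, `min_count = 1`
(clinical corpora are small), `epochs = 5` (the common word2vec default;
on walk corpora of this size more epochs overfit sentence-specific noise
and blur planted synonym pairs). Pretrained vectors in word2vec text
format can be merged in; on vocabulary conflict the corpus-trained vector
wins, and the merge happens before neighbor queries so pretrained words
widen the synonym pool.

## Tree extension: similarity becomes equality

For every non-stopword node whose lemma has cosine neighbors strictly above
`threshold = 0.75`, the forest is extended with one new node per neighbor:
same parent, same incoming relation, and links to the *same* children
(shared by reference, not copied). The added node carries the synonym
lemma and is flagged; it never starts walks, never counts toward repeat
length, and synonyms of added nodes are never expanded (one pass, no
transitive closure). Sharing the children — rather than only mirroring the
incoming edge — is deliberate: it lets a synonym head the same partial
subtree the original heads, without which an inner word of a multi-word
repeat could never be substituted. The printed example selects the *most
similar* words, so the 0.75 cut-off is read as cosine similarity >
0.75 (not distance); the knob is exposed as configuration.

Two tractability guards, absent from the original description, bound
worst-case behavior on degenerate embedding spaces (tiny corpora where
everything resembles everything): at most `max_synonyms = 10` (the most
similar) nodes are grafted per source node, and a candidate subtree keeps
at most `max_forms = 256` synonym-realization forms. On well-trained
spaces neither guard activates.

## Repeat search

A *repeat* is a subtree occurring more than once in the joined tree; a
*full* repeat includes everything reachable from its root, a *partial*
repeat may omit any nodes. Two subtrees are equal iff their canonical
forms are equal, where a form is the node's lemma code followed by the
*sorted* forms of its included children — sorting makes equality invariant
to sibling order, absorbing free word order. Lemmas are interned to
integer codes first; class vertices later receive negative codes so they
can never collide.

The base algorithm (`find_full_repeats`) buckets nodes by classical height
and groups equal full-subtree forms within each bucket. It fails in two
characteristic ways: a phrase repeated with one extra word below it never
matches (full subtrees differ), and the same phrase rooted at different
depths lands in different height buckets. The bundled
`inst/extdata/repeat_examples.conllu` reconstructs both failure cases; the
package's tests assert the base algorithm finds nothing there.

The modified search (`find_partial_repeats`) fixes both. Each node gets an
*array* of heights, one entry per child subtree (a leaf gets `[0]`), so a
node participates at every height its fragments can take. Candidate
subtrees are built bottom-up from combinations of child subtrees
(`enumerate_child_combinations`, all non-empty subsets, fan-out capped at
`max_children = 8` with skip-and-warn); a candidate's bucket is its own
height — the subset's depth, not the node's classical height — which is
what lets the depth-shifted phrase match. When the forest carries added
synonym nodes, each original position may realize its own lemma or any
grafted synonym, so similar phrases produce equal forms. Repeated forms
(at least `min_count = 2` distinct position sets; twice within one
sentence counts) become groups; every occurrence materializes a class
vertex with a fresh negative class code, the occurrence root's incoming
edge, and outgoing edges to that occurrence's chosen children, which makes
the final restoration traversal trivial. Occurrences are always reported
against original sentence nodes, and `max_len = 5` counts words — original
positions — never added nodes, keeping groups short and informative.

Two forms that share an identical occurrence-set collection are synonym
realizations of the same group and are reported once (first form in
height-then-lexicographic order wins). Without added nodes an occurrence
set determines its form uniquely, so this deduplication is a no-op there —
which is also why the search provably agrees with the brute-force oracle.

Nested sub-repeats of a found repeat are reported as their own groups at
every size: reported group-size statistics count small groups separately,
and a configuration switch for maximal-only reporting was deliberately left
out of scope of the defaults.

`oracle_partial_repeats` / `oracle_full_repeats` are independent
correctness references: plain exhaustive enumeration of connected rooted
subtrees, hashed by lemma-based (codec-free) forms, guarded to small
forests. The test suite checks exact agreement of both searches with their
oracles on 1000 seeded random forests, plus the subsumption property that
every full-repeat form reappears among partial forms when the length cap
allows it.

## The knowledge base

The store mirrors a two-table schema: entities (qid, language-tagged name,
normalized name, and the three inheritance relations *instance of*,
*subclass of*, *part of*) and synonyms (alias, normalized alias, target
qid). An entity is *medical* when it carries at least one of 32 fixed
index properties (MeSH, Drugbank, Disease Ontology, eMedicine, ...); the
set is hard-coded from the published list — the filtering from roughly a
hundred candidate knowledge bases down to these 32 was editorial judgment
that cannot be re-derived — and is user-overridable. The live SPARQL path
is isolated behind an injectable query function; everything offline works
from records or the persisted JSON Lines tables. Entities fetched without
a name in the build language are retained only as relation targets and are
unusable for category naming. One language per build (default `"ru"`).

Category resolution follows relation precedence: *instance of* is the
closest category, then *subclass of*, then *part of*; the first relation
with at least one target that exists in the store under a translated name
wins, and *all* named targets of that relation are emitted as co-labels
(real entities frequently carry several instance-of targets, and labeled
examples show multi-label groups).

## Labeling

Groups are labeled in a fixed order; a group may hold labels from several
sources at once:

1. **Vocabularies** — the four domain vocabularies (diseases,
   signs/symptoms, medications, physician specializations), matched against
   each repeat's normalized lemma sequence; multiword terms match
   contiguous subsequences (disease names are routinely multiword, so
   single-word-only matching would be lossy).
2. **Timestamp** — any repeat matching a date pattern: 4-digit years
   1900–2099, `dd.mm.yyyy`-style numeric dates, "day month" phrases.
   Month names are configuration (English and Russian defaults ship).
3. **Event** — a member verb in passive voice (`Voice=Pass`), or a verb
   lemma in a configurable event lexicon. The lexicon exists because the
   printed example "identified in 2009" carries an event label despite
   active morphology; it ships with the admission/assignment/discharge
   verbs plus "identify" (English and Russian).
4. **Knowledge base** — the group's distinct noun/adjective lemmas are
   permuted (k = 1..3; bounded for tractability, the original bound is
   unstated) and each phrase exact-matched against entity names and
   synonyms. Several matching entities are disambiguated by the highest
   cosine between the phrase and each candidate's *category name* — as in
   the worked example cos(pain, negative emotion) = 0.75 vs cos(pain,
   livelihood) = 0.31 — in a skip-gram space trained on the union of the
   KB graph (names, aliases, inheritance edges) and the forest
   (lemma-to-lemma dependency edges), with walk parameters `p = 1`,
   `q = 2`, 3 walks per start, length 5. Out-of-vocabulary candidates rank
   last; remaining ties break by qid. Groups already labeled by a
   vocabulary still go through KB labeling (labeled examples show both
   sources on one group).

The report counts total and covered sentences, labels per source, a label
frequency table, and the two group histograms (words per repeat, repeats
per group).

## The synthetic generator

No real clinical corpus can ship with the package, so `generate_corpus`
emulates the statistical structure the method assumes: free word order
(token order is a random permutation, heads are remapped), planted repeat
templates with exact occurrence counts and depth jitter (re-creating the
height-mismatch scenario), synonym pairs realized by swapping two lemmas
across occurrences of one context template, optional free date tokens and
passive roots, and noise vocabulary disjoint from template lemmas so
planted counts are exact. Ground truth (occurrences with token indices,
labelable sentences, expected coverage) is emitted alongside;
`fixture_resources` builds the matching vocabularies and a small KB, and
`generate_toy_kb` mirrors the published worked examples (an
electrocardiogram-shaped entity with two aliases and all three relations;
two entities sharing the alias "pain"; an untranslated relation target for
the fallback chain).

What the generator does *not* emulate: real morphology and typos, Zipfian
vocabularies, negation/uncertainty, annotation disagreement, or a live
Wikidata snapshot. Green tests therefore demonstrate the *mechanics* —
oracle-exact mining, walk-law convergence, recovery of planted structure —
not clinical-grade annotation accuracy; the published corpus-level numbers
(8.2k groups from 5k sentences, 92.7% label correctness, 82%/97% coverage)
depend on a private Russian EMR corpus and cannot be reproduced at desk
scale.

In the demonstration fixture (`demo_corpus_spec`) each labelable template
carries several fixed context words and 14–16 occurrences in 500
sentences. That is deliberate: embeddings for planted terms must be
well-determined, or the 0.75 threshold grafts spurious synonyms between
label-carrying lemmas and noise, and labels leak into sentences the ground
truth does not mark. At these conditions grafted synonym pairs stay inside
their own templates and the end-to-end coverage check is exact.

## Numerical and engineering choices

- **Determinism**: every source of randomness funnels through explicit
  integer seeds (R's RNG for walks and fixtures, a self-contained xorshift
  RNG inside the C++ trainer); the pipeline derives its stage seeds from
  one master seed. Exact stages (parsing, mining, labeling) are bit-stable
  across reruns; training is bit-stable on one platform and rank-stable
  across platforms.
- **Tie-breaks**: neighbor lists sort by similarity then lexicographically;
  groups sort by form height then form string; disambiguation ties break by
  qid; equal-occurrence forms keep the first form in group order.
- **Degenerate inputs**: empty corpora run end-to-end to an all-zero
  report; an empty embedding space leaves extension as the identity;
  malformed CoNLL-U raises a typed parse error naming sentence and line;
  nodes beyond the fan-out caps are skipped with warnings rather than
  aborting a run.
- **Problem sizes in the test suite** (the package's own choice of scale):
  1000 random forests of up to 8 trees × 10 nodes for oracle equivalence,
  10^5 steps for the walk-law check, a 500-sentence corpus with 20 planted
  pairs for synonym recovery, and the 500-sentence demonstration fixture
  for the end-to-end coverage check.

## Known limitations

- Label leakage is a property of the method, not a bug: similarity groups
  propagate labels by design, so a spurious synonym above threshold labels
  sentences outside any gazetteer hit. On small corpora this dominates;
  the guards bound the cost but not the semantics.
- The partial-repeat enumeration is exponential in principle; `max_len`,
  `max_children` and `max_forms` bound it, at the price of silently
  ignoring repeats wider than the caps.
- Category precedence (*instance of* > *subclass of* > *part of*) is a
  fixed heuristic; published error analysis shows cases where *subclass
  of* is the more meaningful category.
- Coverage counts a sentence as annotated if *any* of its repeats sits in
  *any* labeled group; it says nothing about span-level precision.
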