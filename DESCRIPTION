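Package: syntrep
Title: Unsupervised Mining and Labeling of Repeated Syntactic Constructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and labels repetitive semantic constructions in
    dependency-parsed free text, aimed at clinical corpora in languages that
    lack annotation resources. Sentences in CoNLL-U format are joined into a
    single forest under a virtual root; biased (node2vec-style) random walks
    over the forest feed a word2vec trainer; words with highly similar
    embeddings are grafted into the trees as synonym nodes so that
    similar-subtree search reduces to equal-subtree search; a multi-height
    partial-repeat mining algorithm groups recurring subtrees; groups are
    labeled with domain vocabularies, date/passive-voice heuristics, and a
    Wikidata-derived medical knowledge base with relation-precedence category
    resolution and cosine-based disambiguation. Includes synthetic fixture
    generators, an exhaustive brute-force oracle for the mining algorithms,
    and an end-to-end pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    stringi,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
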