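#' Pipeline configuration
#'
#' Flat key-value configuration for [run_pipeline()], loadable from YAML.
#' Every tunable of the method appears with its standard default: grouping
#' walks p = 2, q = 3, 5 walks per start, length 5; synonym threshold 0.75;
#' repeat length cap 5 words; linking walks p = 1, q = 2, 3 walks per
#' start, length 5. All randomness funnels through the one master `seed`.
#'
#' @param ... Configuration keys (see Details). Unknown keys are an error.
#' @details Keys: `input_conllu` (path or CoNLL-U text), `stopwords`
#'   (path or vector), `weight_map` (path/named vector), `vocabularies`
#'   (named list category -> path, or list of `domain_vocabulary`),
#'   `kb` (a `medical_kb` or a directory for [kb_read()]), `pretrained`
#'   (word2vec text path), `out_dir`, `p`, `q`, `walks_per_start`,
#'   `walk_length`, `cross_sentence`, `dimension`, `window`, `epochs`,
#'   `threshold`, `max_len`, `min_count`, `max_children`, `kb_p`, `kb_q`,
#'   `kb_walks_per_start`, `kb_walk_length`, `max_words`, `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    input_conllu = NULL, stopwords = NULL, weight_map = NULL,
    vocabularies = list(), kb = NULL, pretrained = NULL, out_dir = NULL,
    p = 2, q = 3, walks_per_start = 5, walk_length = 5, cross_sentence = TRUE,
    dimension = 100, window = 5, epochs = 5,
    threshold = 0.75, max_len = 5, min_count = 2, max_children = 8,
    kb_p = 1, kb_q = 2, kb_walks_per_start = 3, kb_walk_length = 5,
    max_words = 3, seed = 1L)
  user <- list(...)
  if (length(user) == 1 && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (k in names(user)) cfg[[k]] <- user[[k]]
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with configuration keys.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full annotation pipeline
#'
#' Stage order: ingest CoNLL-U, flag stopwords, join the forest, generate
#' biased walks and train CBOW embeddings (merging pretrained vectors when
#' provided), graft synonym nodes, mine partial repeats, restore surface
#' sequences, train the linking skip-gram space on the KB-graph/forest
#' union, label groups, and assemble the coverage report. Every stage's
#' output is written under `out_dir` together with a manifest (config
#' hash, seed, package version, stage counts). Reruns with the same config
#' are bit-stable for the exact stages and rank-stable for the trained
#' embeddings.
#'
#' @param config A [pipeline_config()] (or arguments for one, or a YAML
#'   path).
#' @return Invisibly, a list with all in-memory artifacts: `trees`,
#'   `forest`, `walks`, `space`, `extension`, `groups`, `labels`, `report`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(config$input_conllu)) stop("config error: input_conllu is required")
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  log_stage <- function(...) message("[syntrep] ", sprintf(...))

  # ingest ---------------------------------------------------------------
  trees <- read_conllu(config$input_conllu)
  if (!is.null(config$stopwords)) trees <- filter_stopwords(trees, config$stopwords)
  log_stage("ingest: %d sentences, %d tokens", length(trees),
            sum(vapply(trees, function(t) nrow(t$tokens), integer(1))))

  vocabularies <- load_config_vocabularies(config$vocabularies)
  kb <- config$kb
  if (is.character(kb)) kb <- kb_read(kb)

  if (!length(trees)) {
    groups <- structure(list(), class = "repeat_groups")
    ann <- list(labels = empty_labels(),
                report = make_report(groups, empty_labels(), character()))
    res <- list(trees = trees, forest = NULL, walks = list(), space = NULL,
                extension = NULL, groups = groups, labels = ann$labels,
                report = ann$report,
                manifest = pipeline_manifest(config, list(sentences = 0L,
                                                          nodes = 0L, walks = 0L,
                                                          groups = 0L,
                                                          labels = 0L)))
    write_artifacts(config, res)
    return(invisible(res))
  }

  # join + encode --------------------------------------------------------
  forest <- encode_forest(build_joined_forest(trees, config$weight_map))
  log_stage("join: %d forest nodes", nrow(forest$nodes))

  # walks + training -----------------------------------------------------
  wcfg <- walk_config(p = config$p, q = config$q,
                      walks_per_start = config$walks_per_start,
                      walk_length = config$walk_length, seed = config$seed,
                      cross_sentence = config$cross_sentence)
  walks <- generate_walks(forest, wcfg)
  log_stage("walks: %d walks", length(walks))
  space <- NULL
  if (length(walks)) {
    space <- train_embeddings(walks, mode = "cbow", dimension = config$dimension,
                              window = config$window, epochs = config$epochs,
                              seed = config$seed)
    if (!is.null(config$pretrained))
      space <- merge_pretrained(space, read_word2vec(config$pretrained))
    log_stage("train: %d words, dimension %d", nrow(space$vectors),
              ncol(space$vectors))
  }

  # extend ----------------------------------------------------------------
  extension <- NULL
  search_forest <- forest
  if (!is.null(space)) {
    extension <- extend_forest(forest, space, config$threshold)
    search_forest <- extension$forest
    log_stage("extend: %d synonym nodes added", nrow(extension$provenance))
  }

  # mine + restore ---------------------------------------------------------
  groups <- find_partial_repeats(search_forest, max_len = config$max_len,
                                 min_count = config$min_count,
                                 max_children = config$max_children)
  groups <- restore_sequences(search_forest, groups)
  log_stage("repeats: %d groups", length(groups))

  # label ------------------------------------------------------------------
  kb_space <- NULL
  if (!is.null(kb)) {
    kb_space <- train_kb_embeddings(
      kb, forest,
      config = walk_config(p = config$kb_p, q = config$kb_q,
                           walks_per_start = config$kb_walks_per_start,
                           walk_length = config$kb_walk_length,
                           seed = (config$seed + 104729L) %% .Machine$integer.max),
      dimension = config$dimension, window = config$window,
      epochs = config$epochs)
  }
  sentence_ids <- vapply(trees, `[[`, character(1), "sentence_id")
  ann <- annotate_groups(groups, kb, vocabularies, kb_space, sentence_ids,
                         max_words = config$max_words)
  log_stage("label: %d labels, coverage %.3f", nrow(ann$labels),
            ann$report$coverage_fraction)

  res <- list(trees = trees, forest = forest, walks = walks, space = space,
              extension = extension, groups = groups, labels = ann$labels,
              report = ann$report,
              manifest = pipeline_manifest(config, list(
                sentences = length(trees), nodes = nrow(forest$nodes),
                walks = length(walks), groups = length(groups),
                labels = nrow(ann$labels))))
  write_artifacts(config, res)
  invisible(res)
}

load_config_vocabularies <- function(v) {
  if (!length(v)) return(list())
  if (inherits(v[[1]], "domain_vocabulary")) return(v)
  stopifnot(!is.null(names(v)))
  lapply(names(v), function(cat) load_vocabulary(v[[cat]], cat))
}

pipeline_manifest <- function(config, counts) {
  plain <- unclass(config)
  plain <- plain[!vapply(plain, is.object, logical(1))]
  plain$kb <- NULL  # may be an in-memory object; the hash covers scalars
  plain$out_dir <- NULL  # the output location does not affect results
  if (!is.null(plain$vocabularies) && !all(vapply(plain$vocabularies,
                                                  is.character, logical(1))))
    plain$vocabularies <- NULL
  cfg_json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp, useBytes = TRUE)
  h <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(config = plain, config_md5 = h, seed = config$seed,
       package_version = as.character(utils::packageVersion("syntrep")),
       counts = counts)
}

write_artifacts <- function(config, res) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  d <- config$out_dir
  con <- file(file.path(d, "walks.txt"), open = "wb")
  for (w in res$walks) writeLines(paste(w, collapse = " "), con, useBytes = TRUE)
  close(con)
  if (!is.null(res$space)) write_word2vec(res$space, file.path(d, "embeddings.vec"))
  if (!is.null(res$extension))
    write_provenance(res$extension$provenance, file.path(d, "provenance.jsonl"))
  write_groups(res$groups, file.path(d, "groups.jsonl"))
  write_labels(res$labels, file.path(d, "labels.jsonl"))
  writeLines(jsonlite::toJSON(unclass(res$report), auto_unbox = TRUE, digits = NA),
             file.path(d, "report.json"), useBytes = TRUE)
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(d, "manifest.json"), useBytes = TRUE)
  invisible(d)
}
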