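#' Read dependency-parsed sentences from CoNLL-U
#'
#' Parses the standard 10-column CoNLL-U format into a list of sentence
#' trees. Each token keeps its surface form, lemma, universal POS tag,
#' morphological features, head pointer (0 = sentence root) and dependency
#' relation. Multiword-token ranges (`1-2`) and empty nodes (`1.1`) carry no
#' head of their own and are skipped with a warning.
#'
#' @param x Path to a CoNLL-U file, or a character vector of CoNLL-U text
#'   (one string with embedded newlines, or one element per line).
#' @return A list of `sentence_tree` objects. Each is a list with elements
#'   `sentence_id` (string) and `tokens` (data frame with columns `index`,
#'   `form`, `lemma`, `upos`, `feats`, `head`, `deprel`, plus a logical
#'   `excluded` flag used by [filter_stopwords()]).
#' @details Structural validation is strict: a sentence with no root,
#'   several roots, an out-of-range or self-referencing head, or head links
#'   that do not form a tree raises a condition of class
#'   `syntrep_parse_error` carrying the offending sentence id and line
#'   number.
#' @seealso [write_conllu()], [build_joined_forest()]
#' @export
read_conllu <- function(x) {
  lines <- if (length(x) == 1 && (file.exists(x) && !grepl("\n", x))) {
    readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  trees <- list()
  block <- character()
  block_start <- 1L
  n_auto <- 0L
  skipped_ranges <- 0L
  for (i in seq_along(c(lines, ""))) {
    line <- if (i <= length(lines)) lines[[i]] else ""
    if (nzchar(trimws(line))) {
      if (!length(block)) block_start <- i
      block <- c(block, line)
    } else if (length(block)) {
      n_auto <- n_auto + 1L
      parsed <- parse_conllu_block(block, block_start, n_auto)
      skipped_ranges <- skipped_ranges + parsed$skipped
      trees[[length(trees) + 1L]] <- parsed$tree
      block <- character()
    }
  }
  if (skipped_ranges > 0)
    warning(sprintf("skipped %d multiword-token/empty-node line(s)", skipped_ranges),
            call. = FALSE)
  trees
}

parse_error <- function(msg, sentence_id, line) {
  stop(errorCondition(
    sprintf("CoNLL-U parse error in sentence '%s' (line %d): %s", sentence_id, line, msg),
    class = c("syntrep_parse_error", "error", "condition"),
    sentence_id = sentence_id, line = line))
}

parse_conllu_block <- function(block, start_line, n_auto) {
  comments <- block[startsWith(block, "#")]
  data <- block[!startsWith(block, "#")]
  sid <- sub("^#\\s*sent_id\\s*=\\s*", "", comments[grepl("^#\\s*sent_id\\s*=", comments)])
  sid <- if (length(sid)) trimws(sid[[1]]) else sprintf("s%d", n_auto)
  skipped <- 0L
  rows <- vector("list", length(data))
  for (j in seq_along(data)) {
    fields <- strsplit(data[[j]], "\t", fixed = TRUE)[[1]]
    line_no <- start_line + which(block == data[[j]])[1] - 1L
    if (length(fields) != 10)
      parse_error(sprintf("expected 10 tab-separated columns, got %d", length(fields)),
                  sid, line_no)
    id <- fields[[1]]
    if (grepl("[-.]", id)) {  # multiword-token range or empty node
      skipped <- skipped + 1L
      next
    }
    idx <- suppressWarnings(as.integer(id))
    head <- suppressWarnings(as.integer(fields[[7]]))
    if (is.na(idx) || idx < 1) parse_error("bad token index", sid, line_no)
    if (is.na(head) || head < 0) parse_error("bad head", sid, line_no)
    if (!nzchar(fields[[2]])) parse_error("empty form", sid, line_no)
    rows[[j]] <- data.frame(
      index = idx, form = fields[[2]], lemma = fields[[3]], upos = fields[[4]],
      feats = fields[[6]], head = head, deprel = fields[[8]],
      stringsAsFactors = FALSE)
  }
  tokens <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tokens)) tokens <- empty_tokens()
  tokens <- tokens[order(tokens$index), , drop = FALSE]
  rownames(tokens) <- NULL
  tokens$excluded <- FALSE
  tree <- structure(list(sentence_id = sid, tokens = tokens), class = "sentence_tree")
  validate_sentence_tree(tree, start_line)
  list(tree = tree, skipped = skipped)
}

empty_tokens <- function() {
  data.frame(index = integer(), form = character(), lemma = character(),
             upos = character(), feats = character(), head = integer(),
             deprel = character(), stringsAsFactors = FALSE)
}

validate_sentence_tree <- function(tree, line = NA_integer_) {
  tk <- tree$tokens
  n <- nrow(tk)
  if (n == 0) parse_error("sentence has no tokens", tree$sentence_id, line)
  if (!identical(tk$index, seq_len(n)))
    parse_error("token indices are not 1..n", tree$sentence_id, line)
  if (any(tk$head == tk$index))
    parse_error("token is its own head", tree$sentence_id, line)
  if (any(tk$head > n))
    parse_error("head out of range", tree$sentence_id, line)
  roots <- which(tk$head == 0L)
  if (length(roots) != 1)
    parse_error(sprintf("expected exactly one root, found %d", length(roots)),
                tree$sentence_id, line)
  # reachability from the root guarantees the n-1 head links form a tree
  reached <- logical(n)
  frontier <- roots
  reached[frontier] <- TRUE
  while (length(frontier)) {
    frontier <- which(tk$head %in% frontier & !reached)
    reached[frontier] <- TRUE
  }
  if (!all(reached))
    parse_error("head links contain a cycle or disconnected token",
                tree$sentence_id, line)
  invisible(tree)
}

#' @export
print.sentence_tree <- function(x, ...) {
  cat(sprintf("<sentence_tree '%s': %d tokens>\n", x$sentence_id, nrow(x$tokens)))
  invisible(x)
}

#' Serialize sentence trees back to CoNLL-U
#'
#' Inverse of [read_conllu()] on the modeled fields. Columns not modeled
#' (XPOS, DEPS, MISC) are written as `_`, so write-read-write is
#' byte-stable.
#'
#' @param trees List of `sentence_tree` objects.
#' @param path Optional file path; when `NULL` the text is returned.
#' @return The CoNLL-U text as a single string (invisibly when written to
#'   `path`).
#' @export
write_conllu <- function(trees, path = NULL) {
  chunks <- vapply(trees, function(tr) {
    validate_sentence_tree(tr)
    tk <- tr$tokens
    lines <- sprintf("%d\t%s\t%s\t%s\t_\t%s\t%d\t%s\t_\t_",
                     tk$index, tk$form, tk$lemma, tk$upos, tk$feats, tk$head,
                     tk$deprel)
    paste0(paste(c(sprintf("# sent_id = %s", tr$sentence_id), lines),
                 collapse = "\n"), "\n\n")
  }, character(1))
  text <- paste(chunks, collapse = "")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(text, con, sep = "", useBytes = TRUE)
    return(invisible(text))
  }
  text
}

#' Normalize a string for matching
#'
#' The single normal form used everywhere terms are compared: NFC unicode
#' normalization, case folding, whitespace collapsing, and stripping of
#' punctuation surrounding each whitespace-delimited token. Lemmatization is
#' not re-done; the upstream parser's lemma column is trusted.
#'
#' @param x Character vector.
#' @return Character vector of the same length. Idempotent.
#' @examples
#' normalize_text("EKG ")  # "ekg"
#' @export
normalize_text <- function(x) {
  if (!length(x)) return(character())
  out <- stringi::stri_trans_nfc(as.character(x))
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  out <- stringi::stri_trim_both(out)
  # strip punctuation/symbols hugging each token, drop tokens that vanish
  out <- vapply(stringi::stri_split_fixed(out, " "), function(tok) {
    tok <- stringi::stri_replace_all_regex(tok, "^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "")
    paste(tok[nzchar(tok)], collapse = " ")
  }, character(1))
  out[is.na(x)] <- NA_character_
  out
}

#' Flag stopword tokens
#'
#' Marks tokens whose normalized lemma is in `stopwords` as excluded from
#' the walk/embedding vocabulary. Tree structure is untouched, so repeat
#' search still sees the full sentence.
#'
#' @param trees List of `sentence_tree` objects.
#' @param stopwords Character vector of normalized lemmas, or a path to a
#'   UTF-8 file with one lemma per line.
#' @return The trees with the `excluded` token flag set.
#' @export
filter_stopwords <- function(trees, stopwords) {
  if (length(stopwords) == 1 && file.exists(stopwords))
    stopwords <- readLines(stopwords, encoding = "UTF-8", warn = FALSE)
  stopwords <- unique(normalize_text(stopwords))
  stopwords <- stopwords[nzchar(stopwords)]
  lapply(trees, function(tr) {
    tr$tokens$excluded <- normalize_text(tr$tokens$lemma) %in% stopwords
    tr
  })
}
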