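#' Read a raw corpus from a plain-text file
#'
#' Corpora are UTF-8 plain text with pre-tokenized (whitespace-separated)
#' terms. Two dialects are supported: one segment per line (the default;
#' empty lines are skipped), or blank-line-separated blocks where each block
#' of consecutive non-empty lines forms one segment. A segment is the hard
#' context boundary for semantic-space training: sliding windows never cross
#' it.
#'
#' @param path Path to a UTF-8 text file.
#' @param dialect `"line"` (one segment per line) or `"blank"`
#'   (blank-line-separated blocks).
#' @return A list of character vectors, one per segment, named `seg000001`,
#'   `seg000002`, ... in file order. Pass to [preprocess_segments()] to obtain
#'   a corpus.
#' @seealso [preprocess_segments()], [write_corpus()]
#' @export
read_corpus <- function(path, dialect = c("line", "blank")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("cannot read corpus file: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (dialect == "line") {
    keep <- nzchar(trimws(lines))
    chunks <- as.list(lines[keep])
  } else {
    blank <- !nzchar(trimws(lines))
    grp <- cumsum(blank)
    grp <- grp[!blank]
    chunks <- if (length(grp)) {
      lapply(split(lines[!blank], grp), paste, collapse = " ")
    } else {
      list()
    }
  }
  if (length(chunks) == 0L) {
    stop("empty corpus: no non-empty segments in ", path, call. = FALSE)
  }
  segs <- lapply(chunks, function(x) {
    toks <- strsplit(trimws(x), "[[:space:]]+")[[1]]
    toks[nzchar(toks)]
  })
  names(segs) <- sprintf("seg%06d", seq_along(segs))
  segs
}

#' Write segments or a corpus back to disk
#'
#' One segment per line, tokens separated by single spaces; the exact inverse
#' of [read_corpus()] under the line dialect.
#'
#' @param x A corpus (from [preprocess_segments()]) or a raw segment list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  segs <- if (inherits(x, "corpus")) x$segments else x
  writeLines(vapply(segs, paste, "", collapse = " "), path, useBytes = TRUE)
  invisible(path)
}

#' Read a stop-word list
#'
#' One term per line; `#` starts a comment; blank lines ignored. Terms are
#' lowercased to match corpus normalization.
#'
#' @param path Path to a UTF-8 stop-word file.
#' @return Character vector of unique stop words.
#' @export
read_stopwords <- function(path) {
  if (!file.exists(path)) stop("cannot read stop-word file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  terms <- unique(tolower(lines[nzchar(lines)]))
  if (length(terms) == 0L) stop("stop-word list is empty: ", path, call. = FALSE)
  terms
}

# Strip Unicode punctuation and decimal digits from tokens; applied to the
# unique token types only, then mapped back (fast on large corpora).
.clean_tokens <- function(tokens, lowercase) {
  u <- unique(tokens)
  v <- gsub("[\\p{P}\\p{S}\\p{Nd}]+", "", u, perl = TRUE)
  if (lowercase) v <- tolower(v)
  v[match(tokens, u)]
}

#' Normalize raw segments into a corpus
#'
#' Strips punctuation characters and decimal digits from every token
#' (Unicode categories; letters such as a-z and the Swedish characters
#' are kept), optionally lowercases, optionally applies a caller-supplied
#' per-token hook (e.g. an external lemmatizer), and optionally deletes
#' stop words from the token stream (positions close up, so context windows
#' are counted on the filtered stream). Tokens emptied by stripping are
#' dropped; segments emptied entirely are dropped.
#'
#' @param raw Raw segments from [read_corpus()] (or any list of character
#'   vectors), or an existing corpus (its segments are re-normalized).
#' @param stopwords Character vector of stop words, or `NULL`.
#' @param remove_stopwords If `TRUE`, delete stop-word tokens; requires
#'   `stopwords`.
#' @param lowercase Lowercase tokens (default `TRUE`).
#' @param token_fn Optional function applied to each token *before*
#'   normalization (a lemmatizer hook); must map a character vector to a
#'   character vector of the same length.
#' @param name Corpus name recorded in the object.
#' @return A `corpus` object: list with `name`, `segments` (list of character
#'   vectors), `stopwords_removed`, `token_count`, `type_count`.
#' @examples
#' segs <- list(s1 = c("Pat.", "har", "EKG", "2008!"))
#' preprocess_segments(segs, name = "demo")$segments
#' @export
preprocess_segments <- function(raw, stopwords = NULL, remove_stopwords = FALSE,
                                lowercase = TRUE, token_fn = NULL,
                                name = "corpus") {
  segs <- if (inherits(raw, "corpus")) raw$segments else raw
  if (remove_stopwords && is.null(stopwords)) {
    stop("remove_stopwords = TRUE requires a stop-word list", call. = FALSE)
  }
  flat <- unlist(segs, use.names = FALSE)
  if (is.null(flat)) flat <- character(0)
  if (!is.null(token_fn)) flat <- as.character(token_fn(flat))
  flat <- .clean_tokens(flat, lowercase)
  keep <- nzchar(flat)
  if (remove_stopwords) keep <- keep & !(flat %in% stopwords)
  seg_id <- rep.int(seq_along(segs), lengths(segs))
  flat <- flat[keep]
  seg_id <- seg_id[keep]
  out <- split(flat, factor(seg_id, levels = seq_along(segs)))
  names(out) <- names(segs)
  out <- out[lengths(out) > 0L]
  structure(
    list(
      name = name,
      segments = out,
      stopwords_removed = isTRUE(remove_stopwords),
      token_count = length(flat),
      type_count = length(unique(flat))
    ),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf(
    "<corpus '%s'> %d segments, %d tokens, %d types, stop words %s\n",
    x$name, length(x$segments), x$token_count, x$type_count,
    if (x$stopwords_removed) "removed" else "retained"
  ))
  invisible(x)
}

#' Term frequency table of a corpus
#'
#' Exact token counts per term; the counts sum to the corpus token count.
#' Used by [filter_by_frequency()] to restrict reference standards to terms
#' with enough distributional evidence (e.g. at least 50 occurrences).
#'
#' @param corpus A `corpus` object.
#' @return Named integer vector (term -> count), sorted by decreasing count
#'   then term.
#' @export
term_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  if (corpus$token_count == 0L) stop("corpus has no tokens", call. = FALSE)
  flat <- unlist(corpus$segments, use.names = FALSE)
  tab <- table(flat)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts), method = "radix")]
}

#' Write / read a frequency table as 2-column TSV
#'
#' @param counts Named integer vector from [term_frequencies()].
#' @param path TSV path (term TAB count).
#' @return `path` invisibly / the named integer vector.
#' @export
write_frequencies <- function(counts, path) {
  writeLines(paste(names(counts), counts, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path) {
  df <- utils::read.delim(path, header = FALSE, col.names = c("term", "count"),
                          colClasses = c("character", "integer"),
                          quote = "", fileEncoding = "UTF-8")
  counts <- df$count
  names(counts) <- df$term
  counts
}
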