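# Reference-standard management and the evaluation harness: recall@k,
# rank-weighted precision, dev/eval splitting, frequency filtering, the exact
# binomial sign test, and frequency-threshold sweeps.

#' Construct a reference standard
#'
#' A reference standard is a set of term tuples of size >= 2. For the
#' synonym task a tuple is a group of interchangeable terms and every member
#' queries all the others (synonym pairs are queried in both directions). For
#' the abbreviation tasks a tuple is directional: the first element is the
#' abbreviation, the rest are its expansions; `abbr2exp` queries the
#' abbreviation for its expansions and `exp2abbr` queries each expansion for
#' the abbreviation.
#'
#' @param tuples List of character vectors (length >= 2 each).
#' @param task `"syn"`, `"abbr2exp"` or `"exp2abbr"`.
#' @param split_label `"all"`, `"dev"` or `"eval"`.
#' @return A `reference_standard`.
#' @export
reference_standard <- function(tuples, task = c("syn", "abbr2exp", "exp2abbr"),
                               split_label = "all") {
  task <- match.arg(task)
  stopifnot(is.list(tuples), all(lengths(tuples) >= 2L))
  structure(list(task = task, tuples = tuples, split_label = split_label),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  q <- ref_queries(x)
  cat(sprintf("<reference standard: %s, %s> %d tuples, %d queries\n",
              x$task, x$split_label, length(x$tuples), length(q)))
  invisible(x)
}

#' Derive the query -> gold mapping of a reference standard
#'
#' @param ref A [reference_standard()].
#' @return Named list: query term -> character vector of gold terms (merged
#'   across tuples sharing a query term).
#' @export
ref_queries <- function(ref) {
  stopifnot(inherits(ref, "reference_standard"))
  pairs <- lapply(ref$tuples, function(tp) {
    switch(ref$task,
      syn = lapply(seq_along(tp), function(i) list(q = tp[i], g = tp[-i])),
      abbr2exp = list(list(q = tp[1], g = tp[-1])),
      exp2abbr = lapply(tp[-1], function(e) list(q = e, g = tp[1]))
    )
  })
  pairs <- unlist(pairs, recursive = FALSE)
  qs <- vapply(pairs, `[[`, "", "q")
  out <- lapply(split(pairs, qs), function(ps) {
    sort(unique(unlist(lapply(ps, `[[`, "g"), use.names = FALSE)),
         method = "radix")
  })
  out[order(names(out), method = "radix")]
}

#' Load a reference standard from TSV
#'
#' One tuple per line, terms separated by tabs; for the abbreviation tasks
#' column 1 is the abbreviation and the remaining columns its expansions.
#' Terms are lowercased to match corpus normalization. Multiword terms (any
#' internal whitespace) are removed, since the semantic spaces model unigrams
#' only; a tuple left with fewer than two terms is dropped. A line with fewer
#' than two fields is a parse error (reported with its line number).
#'
#' @param path TSV path.
#' @param task Task type, as in [reference_standard()].
#' @return A `reference_standard`.
#' @export
load_reference_standard <- function(path, task = c("syn", "abbr2exp", "exp2abbr")) {
  task <- match.arg(task)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  tuples <- list()
  for (i in which(keep)) {
    fields <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) < 2L) {
      stop(sprintf("parse error in %s line %d: need at least two terms", path, i),
           call. = FALSE)
    }
    fields <- tolower(fields)
    fields <- fields[!grepl("[[:space:]]", fields)]
    if (length(fields) >= 2L) tuples[[length(tuples) + 1L]] <- fields
  }
  if (length(tuples) == 0L) {
    stop("no usable tuples in reference standard: ", path, call. = FALSE)
  }
  reference_standard(tuples, task)
}

#' Write a reference standard as TSV
#' @param ref A [reference_standard()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_reference_standard <- function(ref, path) {
  writeLines(vapply(ref$tuples, paste, "", collapse = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

# Run code with a local RNG seed, leaving the caller's RNG state untouched.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Split a reference standard into development and evaluation halves
#'
#' Whole tuples (not individual queries) are randomly partitioned into two
#' disjoint sets whose sizes differ by at most one; the split is deterministic
#' for a given seed.
#'
#' @param ref A [reference_standard()] with at least 2 tuples.
#' @param seed Integer seed.
#' @return List with elements `dev` and `eval`, both `reference_standard`s.
#' @export
split_dev_eval <- function(ref, seed = 1L) {
  n <- length(ref$tuples)
  if (n < 2L) stop("need at least two tuples to split", call. = FALSE)
  perm <- .with_seed(seed, sample.int(n))
  n_dev <- ceiling(n / 2)
  list(
    dev = reference_standard(ref$tuples[sort(perm[seq_len(n_dev)])], ref$task,
                             split_label = "dev"),
    eval = reference_standard(ref$tuples[sort(perm[-seq_len(n_dev)])], ref$task,
                              split_label = "eval")
  )
}

#' Restrict a reference standard to sufficiently frequent terms
#'
#' A tuple survives only if every one of its terms occurs at least
#' `min_count` times in *every* supplied frequency table — rare terms lack the
#' distributional evidence for a reliable context vector (the conventional
#' threshold is 50 occurrences per corpus).
#'
#' @param ref A [reference_standard()].
#' @param freq_tables A named count vector ([term_frequencies()]) or a list of
#'   them, one per corpus.
#' @param min_count Minimum occurrence count (default 50).
#' @return The filtered `reference_standard` (possibly with zero tuples).
#' @export
filter_by_frequency <- function(ref, freq_tables, min_count = 50L) {
  if (!is.list(freq_tables)) freq_tables <- list(freq_tables)
  stopifnot(length(freq_tables) >= 1L)
  ok <- vapply(ref$tuples, function(tp) {
    all(vapply(freq_tables, function(ft) {
      cnt <- ft[tp]
      cnt[is.na(cnt)] <- 0
      all(cnt >= min_count)
    }, logical(1)))
  }, logical(1))
  out <- ref
  out$tuples <- ref$tuples[ok]
  out
}

.output_terms <- function(x) {
  if (is.null(x)) character(0)
  else if (inherits(x, "candidate_list")) candidate_terms(x)
  else as.character(x)
}

#' Recall at k
#'
#' Micro-averaged over (query, gold term) pairs: the proportion of expected
#' terms that appear among the first `k` suggestions for their query. Queries
#' without an output (e.g. out-of-vocabulary terms) count as misses for all
#' their gold terms.
#'
#' @param outputs Named list (query -> [candidate_list()] or character vector
#'   of suggested terms in rank order).
#' @param ref A [reference_standard()].
#' @param k Suggestion-list length considered (default 10).
#' @return Recall in `[0, 1]`.
#' @export
recall_at_k <- function(outputs, ref, k = 10L) {
  queries <- ref_queries(ref)
  total <- 0L; found <- 0L
  for (q in names(queries)) {
    gold <- queries[[q]]
    sugg <- utils::head(.output_terms(outputs[[q]]), k)
    total <- total + length(gold)
    found <- found + sum(gold %in% sugg)
  }
  if (total == 0L) return(NA_real_)
  found / total
}

#' Rank-weighted precision of one candidate list
#'
#' A true positive at 0-based rank i among the first j suggestions scores
#' j - i; the total is divided by the maximum attainable score (all j
#' suggestions correct): `P_w = sum_{i in tp} (j - i) / sum_{i=0}^{j-1} (j - i)`.
#' Under the fixed mode j is the list length budget (10); under a dynamic
#' cut-off j is the number of candidates actually returned.
#'
#' @param candidates A [candidate_list()] or character vector in rank order.
#' @param gold Character vector of correct terms.
#' @param j Number of labels scored (default 10); longer lists are truncated.
#' @return Weighted precision in `[0, 1]`.
#' @examples
#' weighted_precision(c("a", paste0("x", 1:9)), gold = "a", j = 10) # 10/55
#' @export
weighted_precision <- function(candidates, gold, j = 10L) {
  if (j < 1L) stop("j must be >= 1", call. = FALSE)
  terms <- utils::head(.output_terms(candidates), j)
  hits <- which(terms %in% gold) - 1L
  denom <- sum(j - (seq_len(j) - 1L))
  sum(j - hits) / denom
}

#' Evaluate a set of query outputs against a reference standard
#'
#' @param outputs Named list (query -> [candidate_list()] or character
#'   vector).
#' @param ref A [reference_standard()].
#' @param k List length for recall and (in fixed mode) for weighted precision.
#' @param dynamic If `TRUE`, weighted precision uses j = the returned list
#'   length per query (the dynamic cut-off convention).
#' @return An `eval_report`: list with `per_query` (data.frame: query, n_gold,
#'   n_hits, hit_any, weighted_precision), `recall_at_k`,
#'   `mean_weighted_precision`, `n_queries`, `k`.
#' @export
evaluate_outputs <- function(outputs, ref, k = 10L, dynamic = FALSE) {
  queries <- ref_queries(ref)
  rows <- lapply(names(queries), function(q) {
    gold <- queries[[q]]
    terms <- .output_terms(outputs[[q]])
    jq <- if (dynamic) max(1L, length(terms)) else k
    sugg <- utils::head(terms, k)
    data.frame(
      query = q,
      n_gold = length(gold),
      n_hits = sum(gold %in% sugg),
      hit_any = any(gold %in% sugg),
      weighted_precision = weighted_precision(terms, gold, j = jq),
      stringsAsFactors = FALSE
    )
  })
  per_query <- do.call(rbind, rows)
  structure(
    list(
      per_query = per_query,
      recall_at_k = recall_at_k(outputs, ref, k = k),
      mean_weighted_precision = mean(per_query$weighted_precision),
      n_queries = nrow(per_query),
      k = k
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<evaluation> %d queries | recall@%d = %.3f | weighted precision = %.3f\n",
              x$n_queries, x$k, x$recall_at_k, x$mean_weighted_precision))
  invisible(x)
}

#' Write an evaluation report (JSON detail + TSV summary)
#'
#' @param report An `eval_report`.
#' @param json_path,tsv_path Output paths (`NULL` to skip either).
#' @param label Configuration label for the summary row.
#' @return Invisibly, the summary data.frame.
#' @export
write_eval_report <- function(report, json_path = NULL, tsv_path = NULL,
                              label = "") {
  summary <- data.frame(
    configuration = label,
    n_queries = report$n_queries,
    recall = report$recall_at_k,
    weighted_precision = report$mean_weighted_precision,
    stringsAsFactors = FALSE
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(summary = summary, per_query = report$per_query),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(tsv_path)) {
    utils::write.table(summary, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(summary)
}

#' Exact binomial sign test on paired per-query successes
#'
#' Two-sided: over the discordant pairs (queries where exactly one system
#' succeeds), the number of wins for A is compared with Binomial(n, 1/2);
#' p = min(1, 2 * min(P(X <= k), P(X >= k))). With no discordant pairs the
#' test is uninformative and p = 1. Independence between query terms is
#' assumed.
#'
#' @param hits_a,hits_b Logical vectors of per-query success, same length and
#'   query order.
#' @return The p-value.
#' @export
sign_test_exact <- function(hits_a, hits_b) {
  if (length(hits_a) != length(hits_b)) {
    stop("paired success vectors differ in length", call. = FALSE)
  }
  disc <- hits_a != hits_b
  n <- sum(disc)
  if (n == 0L) return(1)
  k <- sum(hits_a & disc)
  p <- 2 * min(stats::pbinom(k, n, 0.5), 1 - stats::pbinom(k - 1L, n, 0.5))
  min(1, p)
}

#' Frequency-threshold sweep
#'
#' Re-evaluates recall while the minimum corpus frequency required of
#' reference terms rises, reproducing the threshold-sensitivity protocol:
#' for each threshold the reference standard is filtered with
#' [filter_by_frequency()] and recall plus the surviving query count are
#' recorded.
#'
#' @param outputs Named list of query outputs (computed once, at threshold 1).
#' @param ref A [reference_standard()].
#' @param freq_tables Frequency table(s), as in [filter_by_frequency()].
#' @param thresholds Integer vector of thresholds (default 1:100).
#' @param k Suggestion-list length (default 10).
#' @return data.frame with columns `threshold`, `n_tuples`, `n_queries`,
#'   `n_pairs`, `recall`.
#' @export
frequency_sweep <- function(outputs, ref, freq_tables, thresholds = 1:100,
                            k = 10L) {
  rows <- lapply(thresholds, function(th) {
    sub <- filter_by_frequency(ref, freq_tables, min_count = th)
    queries <- if (length(sub$tuples)) ref_queries(sub) else list()
    data.frame(
      threshold = th,
      n_tuples = length(sub$tuples),
      n_queries = length(queries),
      n_pairs = sum(lengths(queries)),
      recall = if (length(queries)) recall_at_k(outputs, sub, k = k) else NA_real_
    )
  })
  do.call(rbind, rows)
}
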