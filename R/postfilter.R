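# Rule-based post-processing of candidate lists.
#
# Abbreviation-expansion candidates are validated structurally (letter
# subsequence with identical initial letters plus length limits); synonym
# candidates are validated by cosine/rank cut-offs tuned per corpus profile.
# Two application modes: a fixed-length top-10 list refilled with the best
# discarded candidates, and a dynamic cut-off returning one to ten accepted
# candidates.

.letters_only <- function(x) {
  gsub("[^\\p{L}]+", "", tolower(x), perl = TRUE)
}

#' Ordered letter-subsequence test with identical initial letters
#'
#' TRUE iff the first letters of `short` and `long` are equal and every letter
#' of `short` occurs in `long` in the same order (greedy scan). Comparison is
#' on lowercased letters; non-letter characters are ignored.
#'
#' @param short,long Non-empty strings (the abbreviation side and the
#'   expansion side).
#' @return Logical.
#' @examples
#' ordered_subsequence_same_initial("ekg", "elektrokardiogram") # TRUE
#' ordered_subsequence_same_initial("kg", "elektrokardiogram")  # FALSE
#' @export
ordered_subsequence_same_initial <- function(short, long) {
  s <- .letters_only(short)
  l <- .letters_only(long)
  if (!nzchar(s) || !nzchar(l)) {
    stop("both strings must contain at least one letter", call. = FALSE)
  }
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  lc <- strsplit(l, "", fixed = TRUE)[[1]]
  if (sc[1] != lc[1]) return(FALSE)
  j <- 1L
  for (ch in sc) {
    repeat {
      if (j > length(lc)) return(FALSE)
      hit <- lc[j] == ch
      j <- j + 1L
      if (hit) break
    }
  }
  TRUE
}

#' Abbreviation-expansion length rule
#'
#' An abbreviation may contain at most `max_abbrev_len` letters (default 4);
#' an expansion must contain at least `min_expansion_len` letters (default 5).
#' Lengths count letters only.
#'
#' @param max_abbrev_len,min_expansion_len Integer bounds.
#' @return An `abbrev_rule`.
#' @export
abbrev_rule <- function(max_abbrev_len = 4L, min_expansion_len = 5L) {
  if (max_abbrev_len >= min_expansion_len) {
    stop("max_abbrev_len must be below min_expansion_len", call. = FALSE)
  }
  structure(list(max_abbrev_len = as.integer(max_abbrev_len),
                 min_expansion_len = as.integer(min_expansion_len)),
            class = "abbrev_rule")
}

.nletters <- function(x) nchar(.letters_only(x))

#' Validate a candidate abbreviation for an expansion query
#'
#' TRUE iff the candidate has at most `max_abbrev_len` letters and its letters
#' form an ordered subsequence of the query expansion with the same initial
#' letter.
#'
#' @param query_expansion The (long-form) query term.
#' @param candidate A suggested short form.
#' @param rule An [abbrev_rule()].
#' @return Logical.
#' @export
accept_exp_to_abbr <- function(query_expansion, candidate, rule = abbrev_rule()) {
  .nletters(candidate) <= rule$max_abbrev_len &&
    ordered_subsequence_same_initial(candidate, query_expansion)
}

#' Validate a candidate expansion for an abbreviation query
#'
#' TRUE iff the candidate has at least `min_expansion_len` letters and the
#' query abbreviation's letters form an ordered subsequence of it with the
#' same initial letter.
#'
#' @param query_abbr The (short-form) query term.
#' @param candidate A suggested expansion.
#' @param rule An [abbrev_rule()].
#' @return Logical.
#' @export
accept_abbr_to_exp <- function(query_abbr, candidate, rule = abbrev_rule()) {
  .nletters(candidate) >= rule$min_expansion_len &&
    ordered_subsequence_same_initial(query_abbr, candidate)
}

#' Synonym cosine/rank cut-off rule
#'
#' A candidate is accepted if any clause is satisfied: cosine at or above the
#' clause threshold and 0-based rank strictly below the clause's rank bound.
#' The shipped profiles reflect cut-offs tuned on clinical and medical
#' development data: `clinical` accepts cos >= 0.60 at any rank or
#' cos >= 0.40 at ranks 0-8; `medical` accepts cos >= 0.50 at any rank;
#' `combined` applies to a four-space summed cosine (maximum value 4) and
#' accepts cos >= 1.9 anywhere, cos >= 1.8 at ranks 0-5, or cos >= 1.75 at
#' ranks 0-2.
#'
#' @param profile `"clinical"`, `"medical"` or `"combined"`; ignored when
#'   `clauses` is given.
#' @param clauses Optional data.frame with columns `cos` and `max_rank`
#'   (use `Inf` for no rank bound) for a custom rule.
#' @return A `synonym_rule`.
#' @export
synonym_rule <- function(profile = c("clinical", "medical", "combined"),
                         clauses = NULL) {
  if (is.null(clauses)) {
    profile <- match.arg(profile)
    clauses <- switch(profile,
      clinical = data.frame(cos = c(0.60, 0.40), max_rank = c(Inf, 9)),
      medical  = data.frame(cos = 0.50, max_rank = Inf),
      combined = data.frame(cos = c(1.9, 1.8, 1.75), max_rank = c(Inf, 6, 3))
    )
  } else {
    profile <- "custom"
    stopifnot(all(c("cos", "max_rank") %in% names(clauses)))
  }
  structure(list(profile = profile, clauses = clauses), class = "synonym_rule")
}

#' Apply a synonym cut-off rule to one candidate
#'
#' @param cos Cosine (or combined cosine) similarity of the candidate.
#' @param rank 0-based rank of the candidate.
#' @param rule A [synonym_rule()].
#' @return Logical.
#' @export
accept_synonym <- function(cos, rank, rule = synonym_rule("clinical")) {
  if (rank < 0) stop("rank must be >= 0", call. = FALSE)
  any(cos >= rule$clauses$cos & rank < rule$clauses$max_rank)
}

#' Ready-made acceptance predicates for [refill_top10()] / [dynamic_cutoff()]
#'
#' `filter_abbrev()` builds a predicate for the abbreviation tasks
#' (direction `"abbr2exp"`: candidates must look like expansions of the query;
#' `"exp2abbr"`: like abbreviations of it). `filter_synonym()` wraps a
#' [synonym_rule()] over each candidate's cosine and rank.
#'
#' @param query The query term (abbreviation side or expansion side).
#' @param direction `"abbr2exp"` or `"exp2abbr"`.
#' @param rule An [abbrev_rule()] / [synonym_rule()].
#' @return A function `(term, score, rank) -> logical`.
#' @export
filter_abbrev <- function(query, direction = c("abbr2exp", "exp2abbr"),
                          rule = abbrev_rule()) {
  direction <- match.arg(direction)
  if (direction == "abbr2exp") {
    function(term, score, rank) accept_abbr_to_exp(query, term, rule)
  } else {
    function(term, score, rank) accept_exp_to_abbr(query, term, rule)
  }
}

#' @rdname filter_abbrev
#' @export
filter_synonym <- function(rule = synonym_rule("clinical")) {
  function(term, score, rank) accept_synonym(score, rank, rule)
}

.classify <- function(candidates, accept, scan_limit) {
  df <- utils::head(candidates$candidates, scan_limit)
  acc <- vapply(seq_len(nrow(df)),
                function(i) isTRUE(accept(df$term[i], df$score[i], df$rank[i])),
                logical(1))
  list(df = df, acc = acc)
}

.filtered_list <- function(candidates, df, accepted_flag, mode) {
  structure(
    list(
      query = candidates$query,
      candidates = data.frame(term = df$term, score = df$score,
                              rank = seq_len(nrow(df)) - 1L,
                              original_rank = df$rank,
                              accepted = accepted_flag,
                              stringsAsFactors = FALSE),
      score_kind = candidates$score_kind,
      source = paste0(candidates$source, " | filtered:", mode)
    ),
    class = "candidate_list"
  )
}

#' Fixed-length filtering with refill
#'
#' Scans the ranked candidate stream (up to `scan_limit` candidates, default
#' 100) collecting candidates the rule accepts, in their original order, until
#' `out_k` (default 10) have been found. If fewer are accepted, the remaining
#' slots are populated with the highest-ranked discarded candidates, so the
#' output always has `out_k` entries when the stream allows. With a rule that
#' accepts everything this reduces to the unfiltered top-`out_k`.
#'
#' @param candidates A [candidate_list()] holding at least the top
#'   `scan_limit` candidates in rank order.
#' @param accept Predicate `(term, score, rank) -> logical`; see
#'   [filter_abbrev()] and [filter_synonym()].
#' @param out_k Output length (default 10).
#' @param scan_limit Number of candidates classified (default 100).
#' @return A `candidate_list` whose candidates carry `original_rank` and
#'   `accepted` columns; empty input gives an empty list.
#' @export
refill_top10 <- function(candidates, accept, out_k = 10L, scan_limit = 100L) {
  cl <- .classify(candidates, accept, scan_limit)
  df <- cl$df; acc <- cl$acc
  take_acc <- utils::head(which(acc), out_k)
  n_pad <- min(out_k, nrow(df)) - length(take_acc)
  take_pad <- utils::head(which(!acc), n_pad)
  idx <- c(take_acc, take_pad)
  .filtered_list(candidates, df[idx, , drop = FALSE],
                 c(rep(TRUE, length(take_acc)), rep(FALSE, length(take_pad))),
                 "refill")
}

#' Dynamic cut-off filtering
#'
#' Returns the accepted candidates (in original order, at most `max_k`) among
#' the first `scan_limit`; if none is accepted, the single rank-0 candidate is
#' returned, so the output always has between one and `max_k` entries for a
#' non-empty stream.
#'
#' @inheritParams refill_top10
#' @param max_k Maximum output length (default 10).
#' @return A `candidate_list` as in [refill_top10()].
#' @export
dynamic_cutoff <- function(candidates, accept, max_k = 10L, scan_limit = 100L) {
  cl <- .classify(candidates, accept, scan_limit)
  df <- cl$df; acc <- cl$acc
  idx <- utils::head(which(acc), max_k)
  if (length(idx) == 0L && nrow(df) > 0L) {
    return(.filtered_list(candidates, df[1L, , drop = FALSE], FALSE, "dynamic"))
  }
  .filtered_list(candidates, df[idx, , drop = FALSE],
                 rep(TRUE, length(idx)), "dynamic")
}
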