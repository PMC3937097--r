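# Combination strategies for ensembles of semantic spaces.
#
# Every strategy consumes per-space similarity "score maps" (term -> cosine,
# query excluded) and produces a single ranked candidate list. Cosine scores
# are only comparable within one space, so several strategies first replace
# scores by 0-based ranks ("normalization"); rank-combined lists sort
# ascending, zero being the best attainable score.

# 0-based descending-score ranks with lexicographic (C locale) tie-break.
.ranks0 <- function(scores) {
  ord <- order(-scores, names(scores), method = "radix")
  r <- integer(length(scores))
  r[ord] <- seq_along(ord) - 1L
  names(r) <- names(scores)
  r
}

#' Replace similarity scores by ranks
#'
#' Rank 0 is the most similar term; ties are broken lexicographically. Terms
#' ranked at or beyond `horizon` are clamped to the penalty rank `horizon`,
#' the same value combiners assign to terms absent from a list altogether
#' (absence from a space must never be an advantage under ascending sort).
#'
#' @param x A [candidate_list()] or a named numeric score map
#'   (higher = more similar).
#' @param horizon Penalty/clamp rank; `NULL` leaves ranks unclamped.
#' @return Named numeric vector of ranks (ascending = better).
#' @export
rank_normalize <- function(x, horizon = NULL) {
  scores <- if (inherits(x, "candidate_list")) {
    stats::setNames(x$candidates$score, x$candidates$term)
  } else {
    x
  }
  r <- .ranks0(scores)
  if (!is.null(horizon)) r <- pmin(r, horizon)
  r
}

# Union of map vocabularies, excluding the query.
.map_union <- function(maps, query) {
  u <- sort(unique(unlist(lapply(maps, names), use.names = FALSE)), method = "radix")
  u[!(u %in% query)]
}

# term x map matrix of values with `fill` for absent terms, plus presence counts.
.map_matrix <- function(maps, terms, fill) {
  M <- matrix(fill, nrow = length(terms), ncol = length(maps),
              dimnames = list(terms, NULL))
  present <- matrix(FALSE, nrow = length(terms), ncol = length(maps))
  for (j in seq_along(maps)) {
    m <- maps[[j]]
    hit <- terms %in% names(m)
    M[hit, j] <- m[terms[hit]]
    present[, j] <- hit
  }
  list(values = M, count = rowSums(present))
}

#' Combine score maps from several semantic spaces
#'
#' The single-step strategies. Without normalization, each candidate's cosine
#' scores are summed over the spaces (`SUM`; a term absent from a space
#' contributes 0 there) or summed and divided by the number of spaces that
#' contain the term (`AVG`, mitigating vocabulary differences between
#' corpora); the combined list sorts descending. With normalization, every
#' map is first replaced by its 0-based ranking (absent terms receiving the
#' penalty rank `horizon`), the per-space ranks are summed (and for `AVG`
#' divided by the containing-space count), and the result sorts ascending
#' with zero the best score.
#'
#' With two maps (an RI and an RP space from one corpus) and `mode = "SUM"`,
#' `normalize = FALSE`, this is the plain RI+RP strategy; with four maps it
#' implements the single-step multi-corpora strategies.
#'
#' @param maps List of at least two named numeric score maps (term -> cosine).
#' @param mode `"SUM"` or `"AVG"`.
#' @param normalize Combine ranks instead of raw scores.
#' @param out_k Number of candidates returned (default 10).
#' @param horizon Penalty rank for terms absent from a map under
#'   `normalize = TRUE`; default: size of the union vocabulary.
#' @param query Query term, excluded from all maps.
#' @param source Provenance tag for the output list.
#' @return A [candidate_list()].
#' @export
combine_scores <- function(maps, mode = c("SUM", "AVG"), normalize = FALSE,
                           out_k = 10L, horizon = NULL, query = character(0),
                           source = "") {
  mode <- match.arg(mode)
  if (length(maps) < 2L) stop("need at least two score maps", call. = FALSE)
  maps <- lapply(maps, function(m) m[!(names(m) %in% query)])
  u <- .map_union(maps, query)
  if (normalize) {
    if (is.null(horizon)) horizon <- length(u)
    rmaps <- lapply(maps, rank_normalize, horizon = horizon)
    mm <- .map_matrix(rmaps, u, fill = horizon)
    comb <- rowSums(mm$values)
    if (mode == "AVG") comb <- comb / mm$count
    kind <- if (mode == "AVG") "rank_avg" else "rank_sum"
  } else {
    mm <- .map_matrix(maps, u, fill = 0)
    comb <- rowSums(mm$values)
    if (mode == "AVG") comb <- comb / mm$count
    kind <- if (mode == "AVG") "averaged_cosine" else "summed_cosine"
  }
  candidate_list(if (length(query)) query[1] else "", comb, score_kind = kind,
                 source = source, k = out_k)
}

#' Subset re-ranking of one space's neighbors by another space
#'
#' The candidate set is the `pool_k` (default 30) nearest neighbors of the
#' query in `pool_space`; those candidates are then ordered by their cosine
#' similarity in `rank_space` (candidates missing from `rank_space`'s
#' vocabulary are dropped) and the list is truncated to `out_k`. Both
#' directions of the published strategy come from the argument order: ranking
#' with RI inside an RP top-30 pool, or ranking with RP inside an RI top-30
#' pool. If fewer than `out_k` candidates survive the pool filter the shorter
#' list is returned.
#'
#' @param rank_space Space whose cosines order the final list.
#' @param pool_space Space whose top-`pool_k` neighbors form the candidate set.
#' @param query Query term (must be in both vocabularies).
#' @param out_k,pool_k Output and pool sizes (defaults 10 and 30).
#' @return A [candidate_list()] with `score_kind = "cosine"` (scores from
#'   `rank_space`).
#' @export
combine_subset <- function(rank_space, pool_space, query, out_k = 10L,
                           pool_k = 30L) {
  pool <- candidate_terms(top_k_neighbors(pool_space, query, k = pool_k))
  rank_map <- .similarity_map(rank_space, query)
  pool <- pool[pool %in% names(rank_map)]
  scores <- rank_map[pool]
  candidate_list(query, scores, score_kind = "cosine",
                 source = sprintf("%s-in-%s%d", rank_space$model,
                                  pool_space$model, pool_k),
                 k = out_k)
}

# Step-1 raw-score combination of one corpus' pair of maps.
.step1 <- function(pair, mode, query) {
  pair <- lapply(pair, function(m) m[!(names(m) %in% query)])
  u <- .map_union(pair, query)
  mm <- .map_matrix(pair, u, fill = 0)
  comb <- rowSums(mm$values)
  if (mode == "AVG") comb <- comb / mm$count
  comb
}

#' Two-step combination of two per-corpus pairs of spaces
#'
#' Each corpus' pair of score maps is first combined over raw cosines with
#' `step1` (`SUM` or `AVG`); the two combined lists are then always
#' rank-normalized, and the normalized lists are combined with `step2`:
#' `SUM` adds the two ranks (a term absent from one corpus' list takes the
#' penalty rank `horizon` there), `AVG` additionally divides by the number of
#' the four source spaces that contain the term. The final list sorts
#' ascending (zero best).
#'
#' @param pair_a,pair_b Lists of named score maps, one pair per corpus.
#' @param step1,step2 `"SUM"` or `"AVG"`.
#' @param out_k Output size (default 10).
#' @param horizon Penalty rank; default: size of the union vocabulary.
#' @param query Query term, excluded everywhere.
#' @return A [candidate_list()] (`rank_sum` or `rank_avg`).
#' @export
combine_two_step <- function(pair_a, pair_b, step1 = c("SUM", "AVG"),
                             step2 = c("SUM", "AVG"), out_k = 10L,
                             horizon = NULL, query = character(0)) {
  step1 <- match.arg(step1); step2 <- match.arg(step2)
  if (length(pair_a) < 2L || length(pair_b) < 2L) {
    stop("each corpus pair needs at least two score maps", call. = FALSE)
  }
  s1a <- .step1(pair_a, step1, query)
  s1b <- .step1(pair_b, step1, query)
  u <- .map_union(list(s1a, s1b), query)
  if (is.null(horizon)) horizon <- length(u)
  ra <- rank_normalize(s1a, horizon = horizon)
  rb <- rank_normalize(s1b, horizon = horizon)
  mm <- .map_matrix(list(ra, rb), u, fill = horizon)
  comb <- rowSums(mm$values)
  kind <- "rank_sum"
  if (step2 == "AVG") {
    src <- .map_matrix(c(pair_a, pair_b), u, fill = 0)
    comb <- comb / src$count
    kind <- "rank_avg"
  }
  candidate_list(if (length(query)) query[1] else "", comb, score_kind = kind,
                 source = sprintf("two-step %s->%s", step1, step2), k = out_k)
}

#' Ensemble configuration
#'
#' Bundles the choices a combination strategy needs; [ensemble_query()]
#' dispatches on it. Strategies: `"SUBSET_RANK_IN_POOL"` (subset re-ranking;
#' the first space ranks, the second pools), `"SCORE_SUM"` / `"SCORE_AVG"`
#' (single-step, optionally rank-normalized), `"TWO_STEP"` (per-corpus
#' combination then combination of combinations; always rank-normalized
#' between the steps).
#'
#' @param strategy One of the four strategy names above.
#' @param normalize Rank-normalize single-step score combination.
#' @param step1_mode,step2_mode `"SUM"`/`"AVG"` for `TWO_STEP`.
#' @param pool_k Pool size for the subset strategy (default 30).
#' @param out_k Returned list length (default 10).
#' @param horizon Penalty rank for absent terms (`NULL`: union-vocabulary
#'   size).
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(strategy = c("SCORE_SUM", "SCORE_AVG",
                                         "SUBSET_RANK_IN_POOL", "TWO_STEP"),
                            normalize = FALSE, step1_mode = "SUM",
                            step2_mode = "SUM", pool_k = 30L, out_k = 10L,
                            horizon = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "SUBSET_RANK_IN_POOL" && pool_k < out_k) {
    stop("pool_k must be at least out_k", call. = FALSE)
  }
  structure(list(strategy = strategy, normalize = normalize,
                 step1_mode = step1_mode, step2_mode = step2_mode,
                 pool_k = as.integer(pool_k), out_k = as.integer(out_k),
                 horizon = horizon),
            class = "ensemble_config")
}

#' Query an ensemble of semantic spaces
#'
#' Computes the per-space score maps for `query` and combines them according
#' to `config`. For `SUBSET_RANK_IN_POOL`, `spaces` must hold exactly two
#' spaces (first = ranking space, second = pool space). For `TWO_STEP`,
#' `spaces` must be a list of two per-corpus lists of spaces. For the
#' score strategies, spaces in which the query is out of vocabulary are
#' skipped; if fewer than two remain, an error of class `synsemble_oov` is
#' raised.
#'
#' @param spaces List of `semantic_space` objects (or, for `TWO_STEP`, a list
#'   of two such lists).
#' @param query Query term.
#' @param config An [ensemble_config()].
#' @return A [candidate_list()].
#' @export
ensemble_query <- function(spaces, query, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  get_map <- function(space) {
    tryCatch(.similarity_map(space, query),
             synsemble_oov = function(e) NULL)
  }
  if (config$strategy == "SUBSET_RANK_IN_POOL") {
    stopifnot(length(spaces) == 2L)
    return(combine_subset(spaces[[1]], spaces[[2]], query,
                          out_k = config$out_k, pool_k = config$pool_k))
  }
  if (config$strategy == "TWO_STEP") {
    stopifnot(length(spaces) == 2L)
    pair_a <- Filter(Negate(is.null), lapply(spaces[[1]], get_map))
    pair_b <- Filter(Negate(is.null), lapply(spaces[[2]], get_map))
    if (length(pair_a) < 2L || length(pair_b) < 2L) {
      .oov_error(query, spaces[[1]][[1]])
    }
    return(combine_two_step(pair_a, pair_b, step1 = config$step1_mode,
                            step2 = config$step2_mode, out_k = config$out_k,
                            horizon = config$horizon, query = query))
  }
  maps <- Filter(Negate(is.null), lapply(spaces, get_map))
  if (length(maps) < 2L) .oov_error(query, spaces[[1]])
  combine_scores(maps,
                 mode = if (config$strategy == "SCORE_AVG") "AVG" else "SUM",
                 normalize = config$normalize, out_k = config$out_k,
                 horizon = config$horizon, query = query,
                 source = config$strategy)
}
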