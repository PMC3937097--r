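# Experiment orchestration: the standard single-corpus space grid, batch
# querying, and the grid evaluation runner.

#' Train the standard grid of semantic spaces for one corpus
#'
#' Four RI spaces (windows 1+1, 2+2, 4+4, 10+10) on the stop-word-filtered
#' corpus and six RP spaces (windows 1+1, 2+2, 4+4; with and without stop
#' words). Spaces are named by total window size: `RI_2`, `RI_4`, `RI_8`,
#' `RI_20`, `RP_2`, `RP_4`, `RP_8` and `RP_*_sw` for the stop-word-retained
#' variants. Optionally cached on disk keyed by name.
#'
#' @param corpus_nosw The corpus with stop words removed (used for RI and the
#'   plain RP spaces).
#' @param corpus_sw The same corpus with stop words retained (used for the
#'   `_sw` RP spaces); pass `NULL` to skip those.
#' @param cfg An [index_config()].
#' @param ri_windows,rp_windows Half-window sizes (defaults 1,2,4,10 and
#'   1,2,4).
#' @param cache_dir If non-`NULL`, spaces are saved there and reloaded on
#'   subsequent calls instead of retrained.
#' @return Named list of `semantic_space` objects.
#' @export
train_space_grid <- function(corpus_nosw, corpus_sw = NULL,
                             cfg = index_config(),
                             ri_windows = c(1L, 2L, 4L, 10L),
                             rp_windows = c(1L, 2L, 4L),
                             cache_dir = NULL) {
  jobs <- list()
  for (w in ri_windows) {
    jobs[[sprintf("RI_%d", 2L * w)]] <- list(model = "RI", w = w, sw = FALSE)
  }
  for (w in rp_windows) {
    jobs[[sprintf("RP_%d", 2L * w)]] <- list(model = "RP", w = w, sw = FALSE)
    if (!is.null(corpus_sw)) {
      jobs[[sprintf("RP_%d_sw", 2L * w)]] <- list(model = "RP", w = w, sw = TRUE)
    }
  }
  spaces <- vector("list", length(jobs))
  names(spaces) <- names(jobs)
  for (nm in names(jobs)) {
    job <- jobs[[nm]]
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(nm, ".space"))
    }
    if (!is.null(cache_file) && file.exists(cache_file)) {
      spaces[[nm]] <- load_space(cache_file)
      next
    }
    corp <- if (job$sw) corpus_sw else corpus_nosw
    spaces[[nm]] <- if (job$model == "RI") {
      train_ri(corp, window_spec(job$w), cfg)
    } else {
      train_rp(corp, window_spec(job$w), cfg)
    }
    if (!is.null(cache_file)) {
      dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
      save_space(spaces[[nm]], cache_file)
    }
  }
  spaces
}

#' The standard grid of RI/RP space pairings
#'
#' Ten combinations per corpus: identical window sizes (1+1, 2+2, 4+4), each
#' with the plain and the stop-word-retaining RP variant, plus the wide RI
#' 10+10 space paired with the narrow RP 1+1 and 2+2 `_sw`/plain variants.
#'
#' @return data.frame with columns `ri` and `rp` (space names as produced by
#'   [train_space_grid()]).
#' @export
standard_grid_combinations <- function() {
  data.frame(
    ri = c("RI_2", "RI_4", "RI_8", "RI_2", "RI_4", "RI_8",
           "RI_20", "RI_20", "RI_20", "RI_20"),
    rp = c("RP_2", "RP_4", "RP_8", "RP_2_sw", "RP_4_sw", "RP_8_sw",
           "RP_2", "RP_4", "RP_2_sw", "RP_4_sw"),
    stringsAsFactors = FALSE
  )
}

# Retrieval for one query under a single-corpus combination strategy.
.single_corpus_query <- function(ri, rp, query, strategy, out_k, pool_k) {
  switch(strategy,
    ri_in_rp30 = combine_subset(ri, rp, query, out_k = out_k, pool_k = pool_k),
    rp_in_ri30 = combine_subset(rp, ri, query, out_k = out_k, pool_k = pool_k),
    ri_plus_rp = combine_scores(
      list(.similarity_map(ri, query), .similarity_map(rp, query)),
      mode = "SUM", out_k = out_k, query = query, source = "RI+RP"),
    stop("unknown strategy: ", strategy, call. = FALSE)
  )
}

#' Batch-query a retrieval function over a reference standard
#'
#' Runs `fn(query)` for every query the reference standard derives;
#' out-of-vocabulary queries yield an empty output (counted as misses by the
#' evaluation).
#'
#' @param fn Function of one query term returning a [candidate_list()].
#' @param ref A [reference_standard()].
#' @return Named list of outputs, one per query.
#' @export
batch_query <- function(fn, ref) {
  queries <- names(ref_queries(ref))
  out <- lapply(queries, function(q) {
    tryCatch(fn(q), synsemble_oov = function(e) character(0))
  })
  names(out) <- queries
  out
}

#' Run the standard single-corpus combination grid
#'
#' For every space pairing of [standard_grid_combinations()] (restricted to
#' the spaces actually present), every requested combination strategy, and
#' every supplied task, evaluates recall@`k` and mean weighted precision over
#' the reference standard.
#'
#' @param spaces Named space list from [train_space_grid()].
#' @param refs Named list of [reference_standard()]s, e.g.
#'   `list(abbr2exp = ..., exp2abbr = ..., syn = ...)`.
#' @param strategies Subset of `c("ri_in_rp30", "rp_in_ri30", "ri_plus_rp")`.
#' @param k Evaluation list length (default 10).
#' @param pool_k Pool size for the subset strategies (default 30).
#' @return data.frame with one row per (combination, strategy, task):
#'   `ri`, `rp`, `strategy`, `task`, `n_queries`, `recall`,
#'   `weighted_precision`.
#' @export
run_standard_grid <- function(spaces, refs,
                              strategies = c("ri_in_rp30", "rp_in_ri30",
                                             "ri_plus_rp"),
                              k = 10L, pool_k = 30L) {
  combos <- standard_grid_combinations()
  combos <- combos[combos$ri %in% names(spaces) & combos$rp %in% names(spaces), ]
  rows <- list()
  for (ci in seq_len(nrow(combos))) {
    ri <- spaces[[combos$ri[ci]]]
    rp <- spaces[[combos$rp[ci]]]
    for (strat in strategies) {
      for (task in names(refs)) {
        ref <- refs[[task]]
        outputs <- batch_query(function(q) {
          .single_corpus_query(ri, rp, q, strat, out_k = k, pool_k = pool_k)
        }, ref)
        rep_ <- evaluate_outputs(outputs, ref, k = k)
        rows[[length(rows) + 1L]] <- data.frame(
          ri = combos$ri[ci], rp = combos$rp[ci], strategy = strat,
          task = task, n_queries = rep_$n_queries, recall = rep_$recall_at_k,
          weighted_precision = rep_$mean_weighted_precision,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}
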