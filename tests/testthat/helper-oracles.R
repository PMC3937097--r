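# Independent oracles and fixture builders shared across the suite.

# Brute-force semantic-space trainer: explicit double loop over positions and
# in-window neighbors, accumulating (weighted / rotated) dense index vectors.
# Deliberately naive and independent of the package's sparse-matrix path.
brute_force_space <- function(corpus, window, cfg, model = c("RI", "RP"),
                              weighted = TRUE) {
  model <- match.arg(model)
  vocab <- sort(unique(unlist(corpus$segments, use.names = FALSE)),
                method = "radix")
  ivs <- lapply(vocab, function(t) index_vector_dense(make_index_vector(t, cfg)))
  names(ivs) <- vocab
  ctx <- matrix(0, length(vocab), cfg$d, dimnames = list(vocab, NULL))
  offsets <- c(if (window[1] > 0) -seq_len(window[1]),
               if (window[2] > 0) seq_len(window[2]))
  for (seg in corpus$segments) {
    n <- length(seg)
    for (i in seq_len(n)) {
      for (p in offsets) {
        j <- i + p
        if (j < 1 || j > n) next
        v <- ivs[[seg[j]]]
        if (model == "RP") v <- rotate(v, p)
        w <- if (model == "RI" && weighted) ri_weight(abs(p)) else 1
        ctx[seg[i], ] <- ctx[seg[i], ] + w * v
      }
    }
  }
  ctx
}

# Random toy corpus: n_tokens tokens over a small vocabulary, cut into
# random-length segments.
random_toy_corpus <- function(n_tokens, vocab_n = 12L, seed = 1L,
                              max_seg_len = 8L) {
  set.seed(seed)
  vocab <- paste0("w", letters[seq_len(vocab_n)])
  toks <- sample(vocab, n_tokens, replace = TRUE)
  cuts <- cumsum(sample.int(max_seg_len, ceiling(n_tokens), replace = TRUE))
  cuts <- cuts[cuts < n_tokens]
  segs <- split(toks, findInterval(seq_len(n_tokens) - 1L, cuts))
  names(segs) <- sprintf("s%03d", seq_along(segs))
  preprocess_segments(segs, name = sprintf("toy%d", seed))
}

# Regex-based ordered-subsequence oracle (same-initial variant), independent
# of the package's greedy scan.
subseq_regex_oracle <- function(short, long) {
  s <- strsplit(tolower(gsub("[^[:alpha:]]", "", short)), "")[[1]]
  l <- tolower(gsub("[^[:alpha:]]", "", long))
  if (length(s) == 0L || !nzchar(l)) stop("empty")
  if (substr(l, 1L, 1L) != s[1]) return(FALSE)
  pat <- paste0("^", paste(s, collapse = ".*"))
  grepl(pat, l)
}

# Exact two-sided sign-test p-value by full enumeration of the binomial tail.
sign_test_enum <- function(n, k) {
  if (n == 0L) return(1)
  pmf <- choose(n, 0:n) / 2^n
  lower <- sum(pmf[seq_len(k + 1L)])
  upper <- sum(pmf[seq.int(k + 1L, n + 1L)])
  min(1, 2 * min(lower, upper))
}

# Semantic space with prescribed cosine similarities to a designated query
# term: query vector is e1, term i's vector is cos_i * e1 + sqrt(1-cos_i^2) *
# e_(i+1). Used to hand-construct retrieval scenarios.
toy_space <- function(query_cosines, query = "q", model = "RI",
                      corpus_name = "toy") {
  terms <- names(query_cosines)
  d <- length(terms) + 1L
  M <- matrix(0, nrow = length(terms) + 1L, ncol = d,
              dimnames = list(c(query, terms), NULL))
  M[query, 1L] <- 1
  for (i in seq_along(terms)) {
    ci <- query_cosines[[i]]
    M[terms[i], 1L] <- ci
    M[terms[i], i + 1L] <- sqrt(1 - ci^2)
  }
  structure(
    list(model = model, window = window_spec(1L),
         stopwords_retained = TRUE, d = d, vectors = M,
         index_config = index_config(d = d, n_nonzero = 2L, seed = 0L),
         corpus_name = corpus_name),
    class = "semantic_space"
  )
}

# A candidate list over synthetic term names t001..t_n with strictly
# decreasing scores, for post-filter stream tests.
numbered_stream <- function(n = 100L, query = "q") {
  terms <- sprintf("t%03d", seq_len(n))
  candidate_list(query, stats::setNames(seq(1, 0.01, length.out = n), terms))
}

tiny_bundle <- function(seed = 42L) {
  generate_bundle(synth_config(
    seed = seed, vocab_size = 300L, n_topics = 4L, n_synonym_pairs = 4L,
    n_abbrev_pairs = 3L, segments_per_corpus = 1500L, segment_length = 8L,
    min_pair_frequency = 25L
  ))
}
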