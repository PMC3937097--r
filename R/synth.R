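# Synthetic two-corpus generator with planted synonym and abbreviation pairs.
#
# The method under test relies on paradigmatic structure: two surface forms of
# the same latent lexeme share neighbors without needing to co-occur. The
# generator creates that structure directly with a topic-mixture background
# (Zipf-distributed word frequencies, topic-boosted) plus, for every planted
# lexeme, a small set of characteristic collocate words emitted around each
# occurrence of either surface form. The two corpora share the vocabulary and
# the lexemes but differ in topic mixture and in which surface form of each
# lexeme dominates (genre skew), emulating genre-distinct clinical vs journal
# text where different corpora contribute complementary candidates.

#' Synthetic-bundle configuration
#'
#' Occurrence counts are scheduled deterministically per lexeme and corpus:
#' the corpus-dispreferred surface form receives `min_pair_frequency`
#' occurrences (times `freq_spread` scaling across lexemes), the preferred
#' form `genre_skew / (1 - genre_skew)` times as many, so every reference
#' term meets the frequency floor in both corpora by construction.
#'
#' @param seed Integer master seed; the whole bundle is a deterministic
#'   function of it.
#' @param vocab_size Background vocabulary size (planted forms and collocates
#'   come on top).
#' @param n_topics Number of background topics.
#' @param n_synonym_pairs Planted synonym pairs (two full-word surface forms
#'   of one lexeme).
#' @param n_abbrev_pairs Planted abbreviation-expansion pairs (the
#'   abbreviation is an ordered letter subsequence of the expansion sharing
#'   its initial letter, at most 4 letters; the expansion has at least 5).
#' @param segments_per_corpus,segment_length Background corpus size; roughly
#'   `segments_per_corpus * segment_length` tokens per corpus before lexeme
#'   windows are spliced in.
#' @param min_pair_frequency Frequency floor guaranteed for every reference
#'   term in each corpus (default 60).
#' @param genre_skew Probability mass of the corpus-preferred surface form,
#'   in `[0.5, 1)` (default 0.8).
#' @param zipf_exponent Zipf exponent of background word frequencies.
#' @param n_collocates Characteristic collocate words per topical cluster,
#'   sampled from the frequent words of the topic; lexemes homed in the same
#'   topic share the set, so planted forms compete with close-relatedness
#'   decoys (realistic confusability).
#' @param collocate_pool Collocates are restricted to the `collocate_pool`
#'   most frequent vocabulary ranks.
#' @param freq_spread Per-lexeme scaling of the occurrence schedule from 1 to
#'   `freq_spread` (default 1: all lexemes at the floor rate; larger values
#'   give the frequency-threshold sweep something to filter).
#' @return A `synth_config`.
#' @export
synth_config <- function(seed = 1L, vocab_size = 1800L, n_topics = 10L,
                         n_synonym_pairs = 20L, n_abbrev_pairs = 10L,
                         segments_per_corpus = 25000L, segment_length = 10L,
                         min_pair_frequency = 60L, genre_skew = 0.8,
                         zipf_exponent = 1.1, n_collocates = 6L,
                         collocate_pool = 120L, freq_spread = 1) {
  cfg <- list(seed = as.integer(seed), vocab_size = as.integer(vocab_size),
              n_topics = as.integer(n_topics),
              n_synonym_pairs = as.integer(n_synonym_pairs),
              n_abbrev_pairs = as.integer(n_abbrev_pairs),
              segments_per_corpus = as.integer(segments_per_corpus),
              segment_length = as.integer(segment_length),
              min_pair_frequency = as.integer(min_pair_frequency),
              genre_skew = genre_skew, zipf_exponent = zipf_exponent,
              n_collocates = as.integer(n_collocates),
              collocate_pool = as.integer(collocate_pool),
              freq_spread = freq_spread)
  n_lex <- cfg$n_synonym_pairs + cfg$n_abbrev_pairs
  if (cfg$vocab_size <= 2L * n_lex) {
    stop("vocab_size must exceed twice the number of planted pairs", call. = FALSE)
  }
  if (cfg$genre_skew < 0.5 || cfg$genre_skew >= 1) {
    stop("genre_skew must lie in [0.5, 1): at 1 the dispreferred surface form ",
         "would never occur and the frequency floor is unachievable", call. = FALSE)
  }
  sched <- .occurrence_schedule(cfg)
  if (sum(sched$total) > cfg$segments_per_corpus) {
    stop("unachievable frequency floor: the occurrence schedule needs ",
         sum(sched$total), " lexeme windows per corpus but only ",
         cfg$segments_per_corpus, " segments are generated", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# Deterministic per-lexeme occurrence counts (dispreferred form at the floor,
# preferred form skew/(1-skew) times as many, linear spread across lexemes).
.occurrence_schedule <- function(cfg) {
  n_lex <- cfg$n_synonym_pairs + cfg$n_abbrev_pairs
  scale <- if (n_lex > 1L) {
    1 + (cfg$freq_spread - 1) * (seq_len(n_lex) - 1L) / (n_lex - 1L)
  } else {
    rep(1, n_lex)
  }
  nonpref <- pmax(cfg$min_pair_frequency,
                  round(cfg$min_pair_frequency * scale))
  pref <- pmax(nonpref, round(nonpref * cfg$genre_skew / (1 - cfg$genre_skew)))
  list(nonpref = nonpref, pref = pref, total = nonpref + pref)
}

# n unique pseudo-word strings of lengths within len_range, disjoint from
# `taken`.
.make_words <- function(n, len_range, taken = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    lens <- sample(seq(len_range[1], len_range[2]), need, replace = TRUE)
    w <- vapply(lens, function(L) {
      paste(sample(letters, L, replace = TRUE), collapse = "")
    }, "")
    out <- unique(c(out, setdiff(w, taken)))
  }
  out[seq_len(n)]
}

# Abbreviation for an expansion: initial letter plus 2-3 further letters in
# order (an ordered subsequence, <= 4 letters).
.make_abbrev <- function(expansion, taken) {
  chars <- strsplit(expansion, "", fixed = TRUE)[[1]]
  repeat {
    k <- sample(2:3, 1L)
    idx <- sort(sample(seq(2L, length(chars)), k))
    ab <- paste(c(chars[1], chars[idx]), collapse = "")
    if (!(ab %in% taken)) return(ab)
  }
}

.build_structure <- function(cfg) {
  vocab <- .make_words(cfg$vocab_size, c(5L, 9L))
  zipf <- (seq_len(cfg$vocab_size))^(-cfg$zipf_exponent)
  topic_of <- sample.int(cfg$n_topics, cfg$vocab_size, replace = TRUE)
  n_lex <- cfg$n_synonym_pairs + cfg$n_abbrev_pairs
  taken <- vocab
  forms <- vector("list", n_lex)
  kind <- character(n_lex)
  for (i in seq_len(cfg$n_synonym_pairs)) {
    f <- .make_words(2L, c(5L, 9L), taken = taken)
    taken <- c(taken, f)
    forms[[i]] <- f
    kind[i] <- "syn"
  }
  for (i in seq_len(cfg$n_abbrev_pairs)) {
    exp_form <- .make_words(1L, c(7L, 10L), taken = taken)
    taken <- c(taken, exp_form)
    ab <- .make_abbrev(exp_form, taken)
    taken <- c(taken, ab)
    forms[[cfg$n_synonym_pairs + i]] <- c(ab, exp_form)
    kind[cfg$n_synonym_pairs + i] <- "abbr"
  }
  home_topic <- rep_len(seq_len(cfg$n_topics), n_lex)
  # Collocates are ordinary words of the lexeme's home topic (restricted to
  # the `collocate_pool` most frequent vocabulary ranks where possible), so
  # they also occur throughout the background text, and the whole set is
  # shared by every lexeme homed in the topic. Planted forms therefore
  # compete with near-neighbor decoys — the other members of their topical
  # cluster, whose expected contexts are identical, and their directly
  # co-occurring collocates — so the gold term is the nearest neighbor only
  # usually, not by construction. This reproduces the central difficulty of
  # real corpora: distributional similarity cannot fully separate synonymy
  # from close topical relatedness.
  topic_shared <- lapply(seq_len(cfg$n_topics), function(t) {
    cand <- which(topic_of == t & seq_len(cfg$vocab_size) <= cfg$collocate_pool)
    if (length(cand) < cfg$n_collocates) cand <- which(topic_of == t)
    sample(cand, min(cfg$n_collocates, length(cand)), prob = zipf[cand])
  })
  collocates <- lapply(seq_len(n_lex), function(i) {
    vocab[topic_shared[[home_topic[i]]]]
  })
  list(vocab = vocab, zipf = zipf, topic_of = topic_of,
       forms = forms, kind = kind,
       home_topic = home_topic, collocates = collocates)
}

# One corpus: background segments from the topic mixture, then scheduled
# lexeme windows ([c c FORM c c], collocate-dominated context) spliced into
# segments of the lexeme's home topic.
.gen_corpus <- function(cfg, st, sched, mixture, pref_idx, name) {
  S <- cfg$segments_per_corpus
  L <- cfg$segment_length
  n_topics <- cfg$n_topics
  boost <- 20
  seg_topic <- sample.int(n_topics, S, replace = TRUE, prob = mixture)
  segs <- vector("list", S)
  for (t in seq_len(n_topics)) {
    which_t <- which(seg_topic == t)
    if (!length(which_t)) next
    p <- st$zipf * ifelse(st$topic_of == t, boost, 1)
    draw <- sample(st$vocab, length(which_t) * L, replace = TRUE, prob = p)
    segs[which_t] <- split(draw, rep(seq_along(which_t), each = L))
  }
  n_lex <- length(st$forms)
  topic_probs <- lapply(seq_len(n_topics), function(t) {
    st$zipf * ifelse(st$topic_of == t, boost, 1)
  })
  for (l in seq_len(n_lex)) {
    pair <- st$forms[[l]]
    pref <- pair[pref_idx[l]]
    nonpref <- pair[3L - pref_idx[l]]
    occ_forms <- c(rep(pref, sched$pref[l]), rep(nonpref, sched$nonpref[l]))
    occ_forms <- sample(occ_forms)
    n_occ <- length(occ_forms)
    t <- st$home_topic[l]
    pool <- which(seg_topic == t)
    if (!length(pool)) pool <- seq_len(S)
    host <- pool[sample.int(length(pool), n_occ, replace = TRUE)]
    use_colloc <- matrix(stats::runif(4L * n_occ) < 0.8, nrow = n_occ)
    ctx_colloc <- matrix(sample(st$collocates[[l]], 4L * n_occ, replace = TRUE),
                         nrow = n_occ)
    ctx_topic <- matrix(sample(st$vocab, 4L * n_occ, replace = TRUE,
                               prob = topic_probs[[t]]), nrow = n_occ)
    ctx <- ifelse(use_colloc, ctx_colloc, ctx_topic)
    for (i in seq_len(n_occ)) {
      win <- c(ctx[i, 1:2], occ_forms[i], ctx[i, 3:4])
      seg <- segs[[host[i]]]
      at <- sample.int(length(seg) + 1L, 1L)
      segs[[host[i]]] <- append(seg, win, after = at - 1L)
    }
  }
  names(segs) <- sprintf("seg%06d", seq_along(segs))
  preprocess_segments(segs, name = name)
}

#' Generate a synthetic two-corpus bundle with planted pairs
#'
#' Produces two genre-distinct corpora plus matching synonym and
#' abbreviation reference standards and full ground-truth metadata. Corpus A
#' prefers the first surface form of each lexeme (for abbreviation lexemes:
#' the short form, telegraphic clinical style); corpus B the second (the
#' expansion, journal style); both forms meet the frequency floor in both
#' corpora. The bundle is a deterministic function of `config$seed`.
#'
#' Post-generation the bundle is verified: every planted abbreviation passes
#' [ordered_subsequence_same_initial()] against its expansion, and every
#' reference term is recounted to meet the floor in each corpus.
#'
#' @param config A [synth_config()].
#' @return A `synth_bundle`: list with `corpus_a`, `corpus_b`, `ref_syn`
#'   (task `"syn"`), `ref_abbr` (task `"abbr2exp"`; re-task with [as_task()]
#'   for the reverse direction), `stopwords` (the most frequent background
#'   words), `truth` (per-lexeme metadata), `config`.
#' @export
generate_bundle <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  sched <- .occurrence_schedule(config)
  st <- .with_seed(config$seed, .build_structure(config))
  n_lex <- length(st$forms)
  pref_a <- rep(1L, n_lex)
  pref_b <- rep(2L, n_lex)
  mix_a <- rev(seq_len(config$n_topics))
  mix_b <- seq_len(config$n_topics)
  seed_a <- (config$seed * 7919 + 1) %% 2147483647
  seed_b <- (config$seed * 7919 + 2) %% 2147483647
  corpus_a <- .with_seed(seed_a,
    .gen_corpus(config, st, sched, mix_a, pref_a, "synthA"))
  corpus_b <- .with_seed(seed_b,
    .gen_corpus(config, st, sched, mix_b, pref_b, "synthB"))
  syn_idx <- which(st$kind == "syn")
  abbr_idx <- which(st$kind == "abbr")
  ref_syn <- reference_standard(st$forms[syn_idx], "syn")
  ref_abbr <- reference_standard(st$forms[abbr_idx], "abbr2exp")
  for (i in abbr_idx) {
    f <- st$forms[[i]]
    stopifnot(nchar(f[1]) <= 4L, nchar(f[2]) >= 5L,
              ordered_subsequence_same_initial(f[1], f[2]))
  }
  fa <- term_frequencies(corpus_a)
  fb <- term_frequencies(corpus_b)
  ref_terms <- unlist(st$forms, use.names = FALSE)
  floor_req <- config$min_pair_frequency
  if (any(is.na(fa[ref_terms])) || any(fa[ref_terms] < floor_req) ||
      any(is.na(fb[ref_terms])) || any(fb[ref_terms] < floor_req)) {
    stop("internal error: a planted term misses its frequency floor", call. = FALSE)
  }
  stopwords <- utils::head(names(fa)[names(fa) %in% st$vocab], 25L)
  truth <- data.frame(
    lexeme = sprintf("lex%03d", seq_len(n_lex)),
    kind = st$kind,
    form_a = vapply(st$forms, `[[`, "", 1L),
    form_b = vapply(st$forms, `[[`, "", 2L),
    home_topic = st$home_topic,
    n_occ_per_corpus = sched$total,
    stringsAsFactors = FALSE
  )
  truth$collocates <- vapply(st$collocates, paste, "", collapse = " ")
  structure(
    list(corpus_a = corpus_a, corpus_b = corpus_b, ref_syn = ref_syn,
         ref_abbr = ref_abbr, stopwords = stopwords, truth = truth,
         config = config),
    class = "synth_bundle"
  )
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic bundle seed=%d> corpora %d/%d tokens, %d synonym pairs, %d abbreviation pairs\n",
    x$config$seed, x$corpus_a$token_count, x$corpus_b$token_count,
    x$config$n_synonym_pairs, x$config$n_abbrev_pairs))
  invisible(x)
}

#' Change the task direction of a reference standard
#'
#' The tuple structure is unchanged (column 1 = abbreviation side); only the
#' direction in which queries are derived changes.
#'
#' @param ref A [reference_standard()].
#' @param task New task type.
#' @return The re-tasked `reference_standard`.
#' @export
as_task <- function(ref, task = c("syn", "abbr2exp", "exp2abbr")) {
  task <- match.arg(task)
  reference_standard(ref$tuples, task, split_label = ref$split_label)
}

#' Write a synthetic bundle to disk
#'
#' Standard formats consumable by every other module: corpus text files (one
#' segment per line), reference-standard TSVs, a stop-word list, and a truth
#' JSON.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_corpus(bundle$corpus_a, file.path(dir, "corpus_a.txt"))
  write_corpus(bundle$corpus_b, file.path(dir, "corpus_b.txt"))
  write_reference_standard(bundle$ref_syn, file.path(dir, "ref_syn.tsv"))
  write_reference_standard(bundle$ref_abbr, file.path(dir, "ref_abbr.tsv"))
  writeLines(bundle$stopwords, file.path(dir, "stopwords.txt"), useBytes = TRUE)
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
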