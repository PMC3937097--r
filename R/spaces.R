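#' Context-window specification
#'
#' @param left,right Number of context positions to the left/right of the
#'   target term. Both non-negative, at least one positive. The common
#'   configurations are 1+1, 2+2, 4+4 and (for RI only, in practice) 10+10.
#' @return A `window_spec` (integer vector of length 2).
#' @export
window_spec <- function(left, right = left) {
  left <- as.integer(left); right <- as.integer(right)
  if (left < 0L || right < 0L || left + right == 0L) {
    stop("window must have left >= 0, right >= 0, left + right > 0", call. = FALSE)
  }
  structure(c(left = left, right = right), class = "window_spec")
}

#' Distance weight for Random Indexing
#'
#' A context term at distance `dist` from the target contributes its index
#' vector scaled by `2^(1 - dist)`: immediate neighbors count fully, and the
#' weight halves with each further step.
#'
#' @param dist Positive integer distance(s) to the target term.
#' @return `2^(1 - dist)`.
#' @examples
#' ri_weight(1:4) # 1, 0.5, 0.25, 0.125
#' @export
ri_weight <- function(dist) {
  if (any(dist < 1)) stop("distance must be >= 1", call. = FALSE)
  2^(1 - dist)
}

#' Circularly shift the elements of a vector
#'
#' The element at index i moves to index (i + offset) mod d. Rotation is a
#' bijection of coordinates, so it preserves norms and pairwise cosines; it is
#' how Random Permutation encodes the signed position of a context term.
#'
#' @param v Numeric vector.
#' @param offset Signed shift (reduced mod `length(v)`); negative = toward
#'   lower indices.
#' @return The rotated vector.
#' @examples
#' rotate(c(1, 0, -1), 1) # c(-1, 1, 0)
#' @export
rotate <- function(v, offset) {
  d <- length(v)
  if (d == 0L) return(v)
  v[((seq_len(d) - 1 - offset) %% d) + 1]
}

# Integer-coded token stream with segment ids; vocabulary sorted (radix) so
# spaces are order-independent.
.corpus_ids <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  tok <- unlist(corpus$segments, use.names = FALSE)
  if (length(tok) == 0L) stop("corpus has an empty vocabulary", call. = FALSE)
  vocab <- sort(unique(tok), method = "radix")
  list(
    id = match(tok, vocab),
    seg = rep.int(seq_along(corpus$segments), lengths(corpus$segments)),
    vocab = vocab
  )
}

# Sparse (V x V) matrix of (target, neighbor) co-occurrence counts at one
# signed offset, truncated at segment boundaries.
.pair_counts <- function(id, seg, offset, V) {
  n <- length(id)
  if (abs(offset) >= n) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(V, V)))
  }
  i1 <- if (offset > 0) seq_len(n - offset) else seq.int(1 - offset, n)
  i2 <- i1 + offset
  ok <- seg[i1] == seg[i2]
  Matrix::sparseMatrix(i = id[i1[ok]], j = id[i2[ok]], x = 1, dims = c(V, V))
}

.train_core <- function(corpus, window, cfg, model, weighted, rotate_iv) {
  stopifnot(inherits(window, "window_spec"), inherits(cfg, "index_config"))
  ids <- .corpus_ids(corpus)
  V <- length(ids$vocab)
  d <- cfg$d
  IV <- .index_matrix(ids$vocab, cfg)
  ctx <- matrix(0, nrow = V, ncol = d)
  offsets <- c(if (window[1] > 0L) -seq_len(window[1]),
               if (window[2] > 0L) seq_len(window[2]))
  for (p in offsets) {
    P <- .pair_counts(ids$id, ids$seg, p, V)
    M <- if (rotate_iv && p %% d != 0) IV[, ((seq_len(d) - 1 - p) %% d) + 1, drop = FALSE] else IV
    w <- if (weighted) ri_weight(abs(p)) else 1
    ctx <- ctx + w * as.matrix(P %*% M)
  }
  rownames(ctx) <- ids$vocab
  structure(
    list(
      model = model,
      window = window,
      stopwords_retained = !isTRUE(corpus$stopwords_removed),
      d = d,
      vectors = ctx,
      index_config = cfg,
      corpus_name = corpus$name
    ),
    class = "semantic_space"
  )
}

#' Train a Random Indexing semantic space
#'
#' For every occurrence of a target term, the index vectors of its in-window
#' neighbors are added to the target's context vector, weighted by
#' [ri_weight()] of the distance (disable with `weighted = FALSE`). Windows
#' are truncated at segment boundaries and distances are counted on the
#' processed token stream (i.e. after any stop-word removal).
#'
#' RI spaces are conventionally trained on stop-word-filtered corpora, since
#' co-occurrence with ubiquitous function words carries little meaning.
#'
#' @param corpus A `corpus` from [preprocess_segments()].
#' @param window A [window_spec()].
#' @param cfg An [index_config()].
#' @param weighted Apply distance weighting (default `TRUE`).
#' @return A `semantic_space` with a dense (vocabulary x d) matrix of context
#'   vectors.
#' @export
train_ri <- function(corpus, window, cfg = index_config(), weighted = TRUE) {
  .train_core(corpus, window, cfg, model = "RI", weighted = weighted,
              rotate_iv = FALSE)
}

#' Train a Random Permutation semantic space
#'
#' Like [train_ri()] but order-aware and unweighted: the index vector of a
#' neighbor at signed offset p (negative = left of the target) is added after
#' [rotate()]-ing its elements by p. Two terms are then close only if they
#' share neighbors *in the same relative positions*. RP spaces are trained
#' both with and without stop words; function words carry syntactic signal
#' that order encoding can exploit.
#'
#' @inheritParams train_ri
#' @param rotations If `FALSE`, force every rotation offset to 0; the model
#'   then degenerates exactly to unweighted RI (a diagnostic, used to validate
#'   the implementation).
#' @return A `semantic_space`.
#' @export
train_rp <- function(corpus, window, cfg = index_config(), rotations = TRUE) {
  .train_core(corpus, window, cfg, model = "RP", weighted = FALSE,
              rotate_iv = rotations)
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf(
    "<semantic space %s %d+%d%s> corpus '%s', %d terms, d=%d, seed=%s\n",
    x$model, x$window[1], x$window[2],
    if (x$stopwords_retained) " (stop words retained)" else "",
    x$corpus_name, nrow(x$vectors), x$d,
    format(x$index_config$seed)
  ))
  invisible(x)
}

#' Terms known to a semantic space
#' @param space A `semantic_space`.
#' @return Character vector of vocabulary terms.
#' @export
space_vocabulary <- function(space) rownames(space$vectors)

#' Save / load a semantic space
#'
#' Versioned plain-text container: a header (model, window, dimensionality,
#' index-vector configuration, corpus name, stop-word flag, vocabulary size)
#' followed by one `term value1 ... value_d` line per vocabulary term with
#' full double precision, i.e. the body doubles as the common text word-vector
#' format (see [export_space_text()]). The round trip is bit-exact.
#'
#' @param space A `semantic_space`.
#' @param path File path.
#' @return `save_space()`: `path` invisibly. `load_space()`: the space.
#' @export
save_space <- function(space, path) {
  stopifnot(inherits(space, "semantic_space"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  header <- c(
    "#synsemble-space v1",
    paste("#model", space$model),
    paste("#window", space$window[1], space$window[2]),
    paste("#d", space$d),
    paste("#n_nonzero", space$index_config$n_nonzero),
    paste("#seed", format(space$index_config$seed, scientific = FALSE)),
    paste("#corpus", space$corpus_name),
    paste("#stopwords_retained", space$stopwords_retained),
    paste("#vocab", nrow(space$vectors))
  )
  writeLines(header, con)
  writeLines(.space_body_lines(space), con)
  invisible(path)
}

.space_body_lines <- function(space) {
  M <- space$vectors
  vals <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  paste(rownames(M), vals)
}

#' @rdname save_space
#' @export
load_space <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) < 10L || lines[1] != "#synsemble-space v1") {
    stop("not a synsemble space file (or unsupported version): ", path,
         call. = FALSE)
  }
  hdr <- lines[2:9]
  field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, " "))]
    if (length(ln) != 1L) stop("corrupt space header: missing ", key, call. = FALSE)
    sub(paste0("^#", key, " "), "", ln)
  }
  d <- as.integer(field("d"))
  nvocab <- as.integer(field("vocab"))
  body <- lines[-(1:9)]
  if (length(body) != nvocab) {
    stop("corrupt or truncated space file: expected ", nvocab,
         " vocabulary rows, found ", length(body), call. = FALSE)
  }
  sp <- strsplit(body, " ", fixed = TRUE)
  if (any(lengths(sp) != d + 1L)) {
    stop("corrupt space file: row with wrong element count", call. = FALSE)
  }
  terms <- vapply(sp, `[[`, "", 1L)
  M <- matrix(as.numeric(unlist(lapply(sp, `[`, -1L), use.names = FALSE)),
              nrow = nvocab, ncol = d, byrow = TRUE)
  rownames(M) <- terms
  win <- as.integer(strsplit(field("window"), " ")[[1]])
  structure(
    list(
      model = field("model"),
      window = window_spec(win[1], win[2]),
      stopwords_retained = as.logical(field("stopwords_retained")),
      d = d,
      vectors = M,
      index_config = index_config(d, as.integer(field("n_nonzero")),
                                  as.numeric(field("seed"))),
      corpus_name = field("corpus")
    ),
    class = "semantic_space"
  )
}

#' Export a space in the plain text word-vector format
#'
#' `term v1 v2 ... v_d`, one line per term, no header; readable by common
#' embedding tooling.
#'
#' @param space A `semantic_space`.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
export_space_text <- function(space, path) {
  writeLines(.space_body_lines(space), path, useBytes = TRUE)
  invisible(path)
}
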