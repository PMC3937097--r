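# Deterministic sparse ternary index vectors.
#
# Each term-as-context is represented by a static d-dimensional vector with
# n_nonzero non-zero elements (half +1, half -1) at pseudo-random positions.
# Positions and signs are derived from a stable 32-bit hash of the term mixed
# with a global seed, so a space is reproducible from (corpus, seed) alone and
# terms can be processed in any order. All arithmetic is done in doubles below
# 2^53, so results are identical across platforms.

# (a * b) mod 2^32 without overflow: split b into 16-bit halves.
.mul32 <- function(a, b) {
  lo <- b %% 65536
  hi <- (b - lo) / 65536
  ((a * lo) %% 4294967296 + ((a * hi) %% 65536) * 65536) %% 4294967296
}

# bitwise xor of 32-bit values held in doubles.
.xor32 <- function(a, b) {
  al <- a %% 65536
  bl <- b %% 65536
  bitwXor((a - al) / 65536, (b - bl) / 65536) * 65536 + bitwXor(al, bl)
}

# Vectorized FNV-1a over Unicode code points, one hash per input string.
.fnv1a32 <- function(strings) {
  n <- length(strings)
  if (n == 0L) return(numeric(0))
  cps <- lapply(strings, utf8ToInt)
  len <- lengths(cps)
  maxlen <- max(len, 1L)
  h <- rep(2166136261, n)
  pad <- function(x) { length(x) <- maxlen; x }
  M <- vapply(cps, pad, numeric(maxlen))
  if (maxlen == 1L) M <- matrix(M, nrow = 1L)
  for (k in seq_len(maxlen)) {
    b <- M[k, ]
    act <- !is.na(b)
    if (!any(act)) break
    h[act] <- .mul32(.xor32(h[act], b[act]), 16777619)
  }
  h
}

# Tempered LCG step; state in [0, 2^32).
.lcg_next <- function(s) (.mul32(s, 1664525) + 1013904223) %% 4294967296
.lcg_out <- function(s) .xor32(s, floor(s / 65536))

#' Index-vector configuration
#'
#' @param d Dimensionality of the space (default 1000).
#' @param n_nonzero Number of non-zero elements per index vector, split evenly
#'   between +1 and -1 (default 8: four 1s and four -1s). Must be even and at
#'   most `d`.
#' @param seed Integer seed mixed into every term hash; spaces trained with the
#'   same `(term, seed)` always assign the term the same index vector.
#' @return An `index_config` list with fields `d`, `n_nonzero`, `seed`.
#' @export
index_config <- function(d = 1000L, n_nonzero = 8L, seed = 1L) {
  d <- as.integer(d); n_nonzero <- as.integer(n_nonzero)
  if (n_nonzero %% 2L != 0L || n_nonzero <= 0L) {
    stop("n_nonzero must be a positive even count", call. = FALSE)
  }
  if (n_nonzero > d) stop("n_nonzero must not exceed d", call. = FALSE)
  structure(list(d = d, n_nonzero = n_nonzero, seed = as.numeric(seed) %% 4294967296),
            class = "index_config")
}

# Draw n distinct positions in 1..d from the term's hash stream.
.draw_positions <- function(state, n, d) {
  pos <- integer(0)
  while (length(pos) < n) {
    state <- .lcg_next(state)
    p <- (.lcg_out(state) %% d) + 1
    if (!(p %in% pos)) pos <- c(pos, p)
  }
  pos
}

#' Generate the index vector of a term
#'
#' Deterministic for a fixed `(term, seed)`: positions and signs come from a
#' pseudo-random stream keyed by a stable hash of the term mixed with the
#' configured seed. The result always has `n_nonzero / 2` elements equal to
#' +1 and `n_nonzero / 2` equal to -1 (element sum is exactly zero).
#'
#' @param term A single term string.
#' @param cfg An [index_config()].
#' @return List with `positions` (1-based, distinct, length `n_nonzero`) and
#'   `signs` (+1/-1, first half +1), plus `d`.
#' @export
make_index_vector <- function(term, cfg = index_config()) {
  stopifnot(inherits(cfg, "index_config"), is.character(term), length(term) == 1L)
  h <- .fnv1a32(term)
  state <- .mul32(.xor32(h, cfg$seed), 2654435761)
  pos <- .draw_positions(state, cfg$n_nonzero, cfg$d)
  half <- cfg$n_nonzero / 2L
  list(positions = as.integer(pos),
       signs = c(rep(1, half), rep(-1, half)),
       d = cfg$d)
}

#' Dense form of an index vector
#'
#' @param iv Result of [make_index_vector()].
#' @return Numeric vector of length `d`.
#' @export
index_vector_dense <- function(iv) {
  v <- numeric(iv$d)
  v[iv$positions] <- iv$signs
  v
}

# Sparse (vocab x d) matrix of index vectors for a whole vocabulary.
# Vectorized bulk path with scalar redraw for the few terms whose first
# n_nonzero draws collide.
.index_matrix <- function(vocab, cfg) {
  V <- length(vocab)
  n <- cfg$n_nonzero
  d <- cfg$d
  h <- .fnv1a32(vocab)
  state <- .mul32(.xor32(h, cfg$seed), 2654435761)
  P <- matrix(0L, nrow = V, ncol = n)
  s <- state
  for (j in seq_len(n)) {
    s <- .lcg_next(s)
    P[, j] <- as.integer((.lcg_out(s) %% d) + 1)
  }
  dup <- which(apply(P, 1L, anyDuplicated) > 0L)
  for (i in dup) P[i, ] <- .draw_positions(state[i], n, d)
  half <- n / 2L
  signs <- rep(c(rep(1, half), rep(-1, half)), times = V)
  Matrix::sparseMatrix(
    i = rep(seq_len(V), each = n),
    j = as.vector(t(P)),
    x = signs,
    dims = c(V, d),
    dimnames = list(vocab, NULL)
  )
}
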