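#' Cosine similarity between two vectors
#'
#' Standard cosine. A term whose context vector is all zero (it was never
#' observed with any in-window neighbor) is treated as maximally dissimilar:
#' the similarity is defined as 0 rather than NaN.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

.oov_error <- function(term, space) {
  stop(structure(
    class = c("synsemble_oov", "error", "condition"),
    list(message = sprintf("query term '%s' is not in the vocabulary of %s space on '%s'",
                           term, space$model, space$corpus_name),
         call = NULL)
  ))
}

# Cosine of `query` against every vocabulary term of a space (query excluded);
# named numeric vector in vocabulary order. Zero-norm rows score 0.
.similarity_map <- function(space, query, exclude = query) {
  M <- space$vectors
  if (!(query %in% rownames(M))) .oov_error(query, space)
  q <- M[query, ]
  norms <- sqrt(rowSums(M^2))
  qn <- sqrt(sum(q^2))
  sims <- if (qn == 0) rep(0, nrow(M)) else as.vector(M %*% q) / (norms * qn)
  sims[norms == 0] <- 0
  names(sims) <- rownames(M)
  sims[!(names(sims) %in% exclude)]
}

#' Construct a ranked candidate list
#'
#' The uniform container for retrieval and ensemble output: candidate terms
#' with scores and consecutive 0-based ranks. Cosine-like score kinds sort
#' descending; rank-based kinds (`rank_sum`, `rank_avg`) sort ascending with
#' zero the best score. Ties are broken lexicographically (C locale) so all
#' outputs are deterministic.
#'
#' @param query The query term (never included among the candidates).
#' @param scores Named numeric vector (term -> score).
#' @param score_kind One of `"cosine"`, `"summed_cosine"`, `"averaged_cosine"`,
#'   `"rank_sum"`, `"rank_avg"`.
#' @param source Free-text provenance tag.
#' @param k Keep at most `k` top candidates (`Inf` = all).
#' @return A `candidate_list`: list with `query`, `candidates`
#'   (data.frame `term`, `score`, `rank`), `score_kind`, `source`.
#' @export
candidate_list <- function(query, scores, score_kind = "cosine", source = "",
                           k = Inf) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  scores <- scores[!(names(scores) %in% query)]
  if (anyDuplicated(names(scores))) stop("duplicate candidate terms", call. = FALSE)
  ascending <- score_kind %in% c("rank_sum", "rank_avg")
  key <- if (ascending) scores else -scores
  ord <- order(key, names(scores), method = "radix")
  if (is.finite(k)) ord <- utils::head(ord, k)
  structure(
    list(
      query = query,
      candidates = data.frame(
        term = names(scores)[ord],
        score = unname(scores[ord]),
        rank = seq_along(ord) - 1L,
        stringsAsFactors = FALSE
      ),
      score_kind = score_kind,
      source = source
    ),
    class = "candidate_list"
  )
}

#' @export
print.candidate_list <- function(x, n = 10L, ...) {
  cat(sprintf("<candidates for '%s'> %s%s, %d terms\n", x$query, x$score_kind,
              if (nzchar(x$source)) paste0(" [", x$source, "]") else "",
              nrow(x$candidates)))
  print(utils::head(x$candidates, n), row.names = FALSE)
  invisible(x)
}

#' Candidate terms of a candidate list, in rank order
#' @param x A `candidate_list`.
#' @return Character vector.
#' @export
candidate_terms <- function(x) x$candidates$term

#' Top-k nearest neighbors of a term in a semantic space
#'
#' Full scan over the vocabulary by cosine similarity; excluded terms (by
#' default the query itself) are removed, ties are broken lexicographically,
#' and ranks run 0, 1, ... If the query is out of vocabulary an error of class
#' `synsemble_oov` is raised so that evaluation code can decide to count the
#' query as a miss.
#'
#' @param space A `semantic_space`.
#' @param query Query term (must be in the vocabulary).
#' @param k Number of neighbors (fewer are returned if the vocabulary is
#'   smaller).
#' @param exclude Terms never to return (default: the query).
#' @return A [candidate_list()] with `score_kind = "cosine"`.
#' @export
top_k_neighbors <- function(space, query, k = 10L, exclude = query) {
  sims <- .similarity_map(space, query, exclude = exclude)
  candidate_list(query, sims, score_kind = "cosine",
                 source = sprintf("%s:%s", space$model, space$corpus_name),
                 k = k)
}

#' Write a candidate list as TSV or JSON
#'
#' @param x A `candidate_list`.
#' @param path Output path.
#' @param format `"tsv"` (rank, term, score) or `"json"`.
#' @return `path` invisibly.
#' @export
write_candidates <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x$candidates[, c("rank", "term", "score")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(query = x$query, score_kind = x$score_kind, source = x$source,
           candidates = x$candidates),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
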