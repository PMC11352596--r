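# Dense candidate generation: embed every gazetteer term, index the
# l2-normalized vectors, and answer top-k concept queries by exhaustive
# cosine scan with per-code max pooling. Exact search is the reference;
# any approximate backend must reproduce it on small indices.

#' Build a term index from gazetteer or training entries
#'
#' Embeds one row per entry (column `term` for gazetteers, `surface` for
#' training sets), l2-normalizes each row, and keeps code/surface
#' alignment. Duplicate surfaces under different codes stay as separate
#' rows: deduplication happens per query, per code, at retrieval time.
#'
#' @param entries A `gazetteer` or `training_set` data frame (any data
#'   frame with a `code` column and a `term` or `surface` column).
#' @param backend An `embedding_backend`.
#' @param batch_size Batch size passed to [embed_terms()].
#' @return An object of class `term_index` with fields `vectors`
#'   (unit-row matrix), `codes`, `surfaces`.
#' @export
build_index <- function(entries, backend, batch_size = 64L) {
  surfaces <- entries$surface %||% entries$term
  if (is.null(surfaces) || length(surfaces) == 0)
    stop_validation("entries must be non-empty and carry term/surface column")
  vec <- embed_terms(backend, surfaces, batch_size)
  vec <- .l2_normalize_rows(vec, "term row")
  structure(list(vectors = vec, codes = as.character(entries$code),
                 surfaces = surfaces),
            class = "term_index")
}

# Rank codes for a scored similarity vector: max pool per code, sort by
# score descending with lexicographic code tie-break, truncate to k.
.rank_codes <- function(sims, codes, k) {
  best <- tapply(sims, codes, max)
  code <- names(best)
  score <- as.numeric(best)
  ord <- order(-score, code, method = "radix")
  take <- seq_len(min(k, length(ord)))
  out <- data.frame(code = code[ord[take]], score = score[ord[take]],
                    stringsAsFactors = FALSE)
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Retrieve the top-k most similar concepts for one mention vector
#'
#' Scores every indexed term by cosine similarity against the normalized
#' query; a code's score is the maximum over its term rows; codes are
#' ranked by score descending with ties broken lexicographically by code.
#'
#' @param index A `term_index`.
#' @param mention_vec Numeric query vector (any positive scale; it is
#'   normalized internally). Must be nonzero.
#' @param k Positive integer; fewer codes are returned when the index has
#'   fewer distinct codes.
#' @return A `candidate_list` data frame with columns `code`, `score`.
#' @export
retrieve <- function(index, mention_vec, k) {
  if (k < 1) stop_validation("k must be at least 1")
  q <- l2_normalize(as.numeric(mention_vec))
  sims <- as.numeric(index$vectors %*% q)
  .rank_codes(sims, index$codes, k)
}

#' Link a batch of mention strings against an index
#'
#' Embeds the mention surfaces with the backend and runs [retrieve()] for
#' each, preserving input order.
#'
#' @param index A `term_index`.
#' @param mentions Character vector of mention surfaces.
#' @param backend An `embedding_backend` (the same one used to build the
#'   index, for meaningful similarities).
#' @param k Candidates per mention.
#' @return A list of `candidate_list` objects, one per mention.
#' @export
link_batch <- function(index, mentions, backend, k) {
  if (length(mentions) == 0) return(list())
  vecs <- embed_terms(backend, mentions)
  lapply(seq_len(nrow(vecs)), function(i) retrieve(index, vecs[i, ], k))
}
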