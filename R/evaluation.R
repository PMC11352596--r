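# Scoring: strict exact-span NER precision/recall/F1 (micro, global
# counts) and NEL top-k accuracy with per-semantic-tag breakdowns.
# Composite mentions are judged on their first gold code.

#' Strict-span NER precision / recall / F1
#'
#' Spans match iff `(doc_id, start, end, label)` are all equal; no partial
#' credit. Empty denominators follow the usual convention: precision is 1
#' when nothing was predicted, recall is 1 when there was nothing to find.
#'
#' @param gold,pred `span_set` data frames.
#' @return A list of class `prf_report` with `precision`, `recall`, `f1`,
#'   `tp`, `fp`, `fn`.
#' @export
ner_prf <- function(gold, pred) {
  gk <- unique(.span_key(gold))
  pk <- unique(.span_key(pred))
  tp <- length(intersect(gk, pk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

# First gold code per mention, validating non-emptiness.
.first_codes <- function(gold) {
  if (any(vapply(gold, length, integer(1)) == 0))
    stop_validation("every gold code list must be non-empty")
  vapply(gold, `[[`, character(1), 1L)
}

#' Top-k linking accuracy
#'
#' A mention counts as correct at k iff its first gold code appears among
#' the first k candidate codes. Candidate lists shorter than k are judged
#' on the available items.
#'
#' @param gold List of character vectors of gold codes (first code is
#'   canonical for composite mentions).
#' @param candidates List of `candidate_list` objects, aligned to `gold`.
#' @param ks Integer vector of cutoffs.
#' @return A list of class `topk_report` with `ks`, `accuracy` (named by
#'   k, non-decreasing) and `n_evaluated`.
#' @export
topk_accuracy <- function(gold, candidates, ks = c(1, 5, 25, 50, 100, 200)) {
  if (length(gold) != length(candidates))
    stop_validation("gold and candidates disagree in length")
  if (length(gold) == 0) stop_validation("nothing to evaluate")
  target <- .first_codes(gold)
  # rank of the gold code in each candidate list (Inf when absent)
  rank_of_gold <- vapply(seq_along(target), function(i) {
    r <- match(target[i], candidates[[i]]$code)
    if (is.na(r)) Inf else as.numeric(r)
  }, numeric(1))
  acc <- vapply(ks, function(k) mean(rank_of_gold <= k), numeric(1))
  if (is.unsorted(acc)) # cannot happen: prefix containment
    stop_training("top-k accuracy must be non-decreasing in k")
  structure(list(ks = as.integer(ks),
                 accuracy = stats::setNames(acc, as.character(ks)),
                 n_evaluated = length(gold)),
            class = "topk_report")
}

#' @export
print.topk_report <- function(x, ...) {
  cat(sprintf("top-k accuracy over %d mentions:\n", x$n_evaluated))
  for (i in seq_along(x$ks))
    cat(sprintf("  k = %3d : %.4f\n", x$ks[i], x$accuracy[i]))
  invisible(x)
}

#' Top-k accuracy broken down by semantic tag
#'
#' Groups mentions by their (literal string) tag and computes accuracy at
#' a single cutoff within each group.
#'
#' @inheritParams topk_accuracy
#' @param tags Character vector, one tag per mention.
#' @param k Single cutoff.
#' @return A data frame with columns `tag`, `accuracy`, `n`, one row per
#'   non-empty group, sorted by descending `n` then tag.
#' @export
per_tag_accuracy <- function(gold, candidates, tags, k) {
  if (length(tags) != length(gold))
    stop_validation("tags and gold disagree in length")
  groups <- split(seq_along(gold), tags)
  rows <- lapply(names(groups), function(tg) {
    idx <- groups[[tg]]
    rep <- topk_accuracy(gold[idx], candidates[idx], ks = k)
    data.frame(tag = tg, accuracy = unname(rep$accuracy), n = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$n, out$tag, method = "radix"), , drop = FALSE]
}
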