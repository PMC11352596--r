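# Sequence-labeling plumbing: offset-preserving sentence segmentation,
# IOB encoding/decoding against an offset-producing tokenizer, and
# exact-span majority voting over the span sets of several NER models.
# All character offsets are 0-based half-open at document level.

.abbrev_guard <- c("sr", "sra", "dr", "dra", "d", "p", "ej", "etc", "fig",
                   "no", "vs", "aprox", "art", "pag", "ud", "uds")

# Substring by 0-based half-open offsets.
.slice <- function(text, start, end) substr(text, start + 1L, end)

#' Split a document into sentences, preserving offsets
#'
#' Boundaries are sentence-final punctuation (`. ! ? ;`) followed by
#' whitespace, and newlines. A period is not a boundary when the word it
#' terminates is a single letter or a known clinical/Spanish abbreviation
#' (e.g. "p. ej."). Sentences are trimmed of surrounding whitespace; the
#' characters between consecutive sentence spans are exactly the skipped
#' separators, so the document reconstructs.
#'
#' @param doc_id Document identifier carried onto every sentence.
#' @param text Non-empty document text.
#' @return A data frame of class `sentence_set` with columns `doc_id`,
#'   `start`, `end`, `text`; `substr(text, start+1, end)` of the document
#'   equals each sentence's `text`.
#' @export
split_sentences <- function(doc_id, text) {
  if (!nzchar(text)) stop_validation("text must be non-empty")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  boundary_after <- logical(n)        # sentence ends AFTER this index
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch == "\n") {
      boundary_after[i] <- TRUE
    } else if (ch %in% c("!", "?", ";", ".") &&
               (i == n || grepl("^\\s$", chars[i + 1]))) {
      if (ch == ".") {
        # word immediately before the period
        j <- i - 1L
        while (j >= 1 && grepl("^[[:alnum:]]$", chars[j])) j <- j - 1L
        word <- tolower(paste(chars[seq(j + 1L, length.out = i - 1L - j)],
                              collapse = ""))
        if (nchar(word) == 1 || word %in% .abbrev_guard) next
      }
      boundary_after[i] <- TRUE
    }
  }
  ends <- c(which(boundary_after), n)
  ends <- unique(ends)
  spans <- list()
  cursor <- 0L                         # 0-based start of the next segment
  for (e in ends) {
    seg_start <- cursor; seg_end <- e  # raw segment, half-open
    cursor <- e
    raw <- .slice(text, seg_start, seg_end)
    lead <- nchar(sub("^(\\s*).*$", "\\1", raw))
    trail <- nchar(raw) - nchar(sub("\\s+$", "", raw))
    s <- seg_start + lead
    t <- seg_end - trail
    if (s >= t) next                   # whitespace-only segment
    spans[[length(spans) + 1]] <- data.frame(
      doc_id = doc_id, start = s, end = t,
      text = .slice(text, s, t), stringsAsFactors = FALSE)
  }
  if (length(spans) == 0)
    stop_validation("text contains no non-whitespace characters")
  out <- do.call(rbind, spans)
  class(out) <- c("sentence_set", "data.frame")
  out
}

#' Whitespace tokenizer with character offsets
#'
#' Returns a tokenizer satisfying the offset contract used by [to_iob()]:
#' a function mapping a string to a data frame with columns `surface`,
#' `start`, `end` (0-based half-open, relative to the input string).
#'
#' @return A tokenizer function.
#' @export
whitespace_tokenizer <- function() {
  function(text) {
    m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
    if (m[1] == -1)
      return(data.frame(surface = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    start <- as.integer(m) - 1L
    end <- start + attr(m, "match.length")
    data.frame(surface = substring(text, start + 1L, end),
               start = start, end = end, stringsAsFactors = FALSE)
  }
}

#' Encode one sentence's mentions as an IOB tag sequence
#'
#' Tokens overlapping a mention span get `B-<label>` (first token) and
#' `I-<label>` (subsequent tokens); a token that only partially overlaps a
#' mention is included in it whole. Mentions must not overlap each other.
#'
#' @param sentence One row of a `sentence_set` (document-level offsets).
#' @param mentions A `mention_set` whose spans lie within the sentence.
#' @param tokenizer An offset-producing tokenizer; defaults to
#'   [whitespace_tokenizer()].
#' @return A list of class `iob_sequence` with `tokens` (data frame with
#'   sentence-relative offsets) and `tags` (character vector).
#' @export
to_iob <- function(sentence, mentions, tokenizer = whitespace_tokenizer()) {
  toks <- tokenizer(sentence$text)
  tags <- rep("O", nrow(toks))
  if (!is.null(mentions) && nrow(mentions) > 0) {
    ms <- mentions$start - sentence$start   # sentence-relative
    me <- mentions$end - sentence$start
    if (any(ms < 0) || any(me > nchar(sentence$text)))
      stop_validation("mention outside the sentence span")
    ord <- order(ms)
    if (any(ms[ord][-1] < me[ord][-length(ord)])) {
      i <- which(ms[ord][-1] < me[ord][-length(ord)])[1]
      stop_validation("overlapping gold mentions: [%d,%d) and [%d,%d)",
                      ms[ord][i], me[ord][i], ms[ord][i + 1], me[ord][i + 1])
    }
    for (j in ord) {
      hit <- which(toks$start < me[j] & toks$end > ms[j])
      if (length(hit) == 0) next
      tags[hit[1]] <- paste0("B-", mentions$label[j])
      if (length(hit) > 1)
        tags[hit[-1]] <- paste0("I-", mentions$label[j])
    }
  }
  structure(list(tokens = toks, tags = tags), class = "iob_sequence")
}

#' Decode an IOB tag sequence back into spans
#'
#' Maximal `B-L (I-L)*` runs become predicted spans at document-level
#' offsets (the sentence start is added back). An orphan `I-L` (not
#' preceded by `B-L`/`I-L` of the same label) is repaired to `B-L` with a
#' warning, so every tag sequence decodes.
#'
#' @param seq An `iob_sequence`.
#' @param sentence The sentence the sequence was encoded against.
#' @return A data frame of class `span_set` with columns `doc_id`, `start`,
#'   `end`, `label`.
#' @export
from_iob <- function(seq, sentence) {
  tags <- seq$tags
  toks <- seq$tokens
  # repair orphan I-tags
  prev_label <- ""
  repaired <- FALSE
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (startsWith(tg, "I-")) {
      lab <- substring(tg, 3)
      if (prev_label != lab) {
        tags[i] <- paste0("B-", lab)
        repaired <- TRUE
      }
      prev_label <- lab
    } else if (startsWith(tg, "B-")) {
      prev_label <- substring(tg, 3)
    } else {
      prev_label <- ""
    }
  }
  if (repaired) warn_wntlink("orphan I- tag(s) repaired to B-")
  spans <- list()
  i <- 1L
  while (i <= length(tags)) {
    if (startsWith(tags[i], "B-")) {
      lab <- substring(tags[i], 3)
      j <- i
      while (j + 1L <= length(tags) && tags[j + 1L] == paste0("I-", lab))
        j <- j + 1L
      spans[[length(spans) + 1]] <- data.frame(
        doc_id = sentence$doc_id,
        start = sentence$start + toks$start[i],
        end = sentence$start + toks$end[j],
        label = lab, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- if (length(spans) == 0)
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               label = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, spans)
  class(out) <- c("span_set", "data.frame")
  out
}

.span_key <- function(spans)
  paste(spans$doc_id, spans$start, spans$end, spans$label, sep = "\r")

#' Exact-span majority voting over ensemble member predictions
#'
#' A span `(doc_id, start, end, label)` is kept iff it appears, exactly
#' matched, in at least `min_votes` member span sets (each member counted
#' once per span). Kept spans are deduplicated and sorted; overlaps among
#' kept spans are retained as-is.
#'
#' @param predictions A list of `span_set` data frames, one per ensemble
#'   member.
#' @param min_votes Votes required to keep a span; defaults to a strict
#'   majority `floor(M/2) + 1` of the `M` members.
#' @return A `span_set` of the spans that won the vote.
#' @export
majority_vote <- function(predictions, min_votes = NULL) {
  M <- length(predictions)
  if (M < 1) stop_validation("at least one member prediction is required")
  min_votes <- min_votes %||% (M %/% 2L + 1L)
  if (min_votes < 1 || min_votes > M)
    stop_validation("min_votes must lie in [1, %d]", M)
  all_spans <- do.call(rbind, lapply(predictions, function(p) {
    p <- as.data.frame(p)[, c("doc_id", "start", "end", "label")]
    p[!duplicated(.span_key(p)), , drop = FALSE]
  }))
  if (nrow(all_spans) == 0) {
    out <- all_spans
  } else {
    key <- .span_key(all_spans)
    votes <- table(key)
    keep_keys <- names(votes)[votes >= min_votes]
    out <- all_spans[match(keep_keys, key), , drop = FALSE]
    out <- out[order(out$doc_id, out$start, out$end, out$label,
                     method = "radix"), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("span_set", "data.frame")
  out
}
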