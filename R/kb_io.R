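# Gazetteer / annotation file IO and training-set construction.
#
# File dialect (tab-separated, UTF-8, header row):
#   gazetteer:   code  language  term  semantic_tag  mainterm
#   annotations: filename  label  start_span  end_span  text  [code]
# Composite codes are "+"-joined in the code column; the sentinel NO_CODE
# marks a mention that was left unnormalized by the annotators.

NO_CODE_SENTINEL <- "NO_CODE"

.read_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", colClasses = "character",
                    check.names = FALSE, encoding = "UTF-8",
                    stringsAsFactors = FALSE)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
}

.trimws2 <- function(x) trimws(x, which = "both")

#' Read a concept gazetteer
#'
#' Parses a tab-separated gazetteer mapping concept codes to surface terms.
#' Required columns: `code`, `language`, `term`, `semantic_tag`, `mainterm`.
#' Duplicate `(code, term, language)` rows are collapsed to one with a
#' warning; `code` and `term` must be non-empty after trimming.
#'
#' @param path Path to a tab-separated gazetteer file with header row.
#' @return A data frame of class `gazetteer` with columns `code`, `term`,
#'   `semantic_tag`, `language`, `is_main_term` (logical).
#' @export
load_gazetteer <- function(path) {
  df <- .read_tsv(path)
  .require_columns(df, c("code", "language", "term", "semantic_tag",
                         "mainterm"), path)
  code <- .trimws2(df$code)
  term <- .trimws2(df$term)
  bad <- which(code == "" | term == "")
  if (length(bad) > 0)
    stop_validation("%s: empty code or term at file line %d",
                    path, bad[1] + 1L)  # +1 for the header row
  key <- paste(code, term, df$language, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warn_wntlink("%s: %d duplicated (code, term, language) row(s) collapsed",
                 path, sum(dup))
  }
  keep <- !dup
  out <- data.frame(code = code[keep], term = term[keep],
                    semantic_tag = .trimws2(df$semantic_tag)[keep],
                    language = .trimws2(df$language)[keep],
                    is_main_term = df$mainterm[keep] %in% c("1", "true", "TRUE", "True"),
                    stringsAsFactors = FALSE)
  class(out) <- c("gazetteer", "data.frame")
  out
}

#' Write a gazetteer in the package dialect
#'
#' Inverse of [load_gazetteer()]: round-tripping a parsed gazetteer through
#' `write_gazetteer` and `load_gazetteer` yields an identical entry table.
#'
#' @param gazetteer A `gazetteer` data frame.
#' @param path Output path.
#' @export
write_gazetteer <- function(gazetteer, path) {
  out <- data.frame(code = gazetteer$code, language = gazetteer$language,
                    term = gazetteer$term,
                    semantic_tag = gazetteer$semantic_tag,
                    mainterm = as.integer(gazetteer$is_main_term),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read mention annotations
#'
#' Parses a tab-separated mention file: one character-span mention per row,
#' offsets 0-based half-open. With `with_codes = TRUE` a `code` column of
#' "+"-joined concept identifiers is parsed into a code list per mention;
#' the sentinel `NO_CODE` yields an empty code list.
#'
#' @param path Path to a tab-separated annotation file with header row
#'   (`filename`, `label`, `start_span`, `end_span`, `text`, and `code` when
#'   `with_codes`).
#' @param with_codes Whether the file carries gold concept codes.
#' @return A data frame of class `mention_set` with columns `doc_id`,
#'   `label`, `start`, `end`, `text` and a list-column `codes`.
#' @export
load_annotations <- function(path, with_codes = TRUE) {
  df <- .read_tsv(path)
  cols <- c("filename", "label", "start_span", "end_span", "text")
  if (with_codes) cols <- c(cols, "code")
  .require_columns(df, cols, path)
  if (!all(grepl("^[0-9]+$", df$start_span)) ||
      !all(grepl("^[0-9]+$", df$end_span)))
    stop_format("%s: non-integer character offsets", path)
  start <- as.integer(df$start_span)
  end <- as.integer(df$end_span)
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop_validation("%s: start_span >= end_span at file line %d",
                    path, bad[1] + 1L)
  codes <- if (with_codes) {
    lapply(.trimws2(df$code), function(cc) {
      if (cc == NO_CODE_SENTINEL || cc == "") character(0)
      else strsplit(cc, "+", fixed = TRUE)[[1]]
    })
  } else {
    rep(list(character(0)), nrow(df))
  }
  out <- data.frame(doc_id = df$filename, label = df$label,
                    start = start, end = end, text = df$text,
                    stringsAsFactors = FALSE)
  out$codes <- codes
  class(out) <- c("mention_set", "data.frame")
  out
}

#' Write mention annotations in the package dialect
#'
#' @param mentions A `mention_set` data frame.
#' @param path Output path.
#' @param with_codes Whether to emit the `code` column ("+"-joined;
#'   `NO_CODE` for mentions with no codes).
#' @export
write_annotations <- function(mentions, path, with_codes = TRUE) {
  out <- data.frame(filename = mentions$doc_id, label = mentions$label,
                    start_span = mentions$start, end_span = mentions$end,
                    text = mentions$text, stringsAsFactors = FALSE)
  if (with_codes) {
    out$code <- vapply(mentions$codes, function(cc) {
      if (length(cc) == 0) NO_CODE_SENTINEL else paste(cc, collapse = "+")
    }, character(1))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Enrich a surface form with its semantic tag
#'
#' Training surfaces take the form `"term [tag]"`; when the tag is empty the
#' term passes through unchanged. The suffix is appended verbatim (no
#' escaping), so a term already containing brackets keeps them.
#'
#' @param term Character vector of non-empty surface strings.
#' @param semantic_tag Character vector of tags (may be empty strings).
#' @return Character vector of enriched surfaces.
#' @export
format_training_term <- function(term, semantic_tag) {
  if (any(!nzchar(term))) stop_validation("empty term cannot be formatted")
  semantic_tag <- rep_len(as.character(semantic_tag), length(term))
  ifelse(nzchar(semantic_tag),
         paste0(term, " [", semantic_tag, "]"),
         term)
}

#' Build the head-training set from mentions plus gazetteer
#'
#' Concatenates the coded mention surfaces (first code of a composite
#' mention is the canonical one) with every gazetteer entry, each surface
#' enriched with its concept's semantic tag via [format_training_term()].
#' Mentions come first, then gazetteer entries, both in input order.
#'
#' @param mentions A `mention_set`; mentions with no codes must already be
#'   removed.
#' @param gazetteer A `gazetteer` data frame.
#' @param tag_lookup Optional named character vector mapping code to
#'   semantic tag (used for mention surfaces). Defaults to the first tag
#'   seen per code in the gazetteer; codes without a tag get none.
#' @return A data frame of class `training_set` with columns `surface`,
#'   `code`, `source` (`"mention"` or `"gazetteer"`).
#' @export
build_training_set <- function(mentions, gazetteer, tag_lookup = NULL) {
  if (is.null(tag_lookup)) {
    first <- !duplicated(gazetteer$code)
    tag_lookup <- stats::setNames(gazetteer$semantic_tag[first],
                                  gazetteer$code[first])
  }
  n_m <- if (is.null(mentions)) 0L else nrow(mentions)
  if (n_m > 0) {
    n_codes <- vapply(mentions$codes, length, integer(1))
    if (any(n_codes == 0))
      stop_validation("mentions with empty code lists must be removed first")
    m_code <- vapply(mentions$codes, `[[`, character(1), 1L)
    m_tag <- unname(tag_lookup[m_code])
    m_tag[is.na(m_tag)] <- ""
    m_surface <- format_training_term(mentions$text, m_tag)
  } else {
    m_code <- character(0); m_surface <- character(0)
  }
  g_surface <- format_training_term(gazetteer$term, gazetteer$semantic_tag)
  out <- data.frame(
    surface = c(m_surface, g_surface),
    code = c(m_code, gazetteer$code),
    source = c(rep("mention", length(m_surface)),
               rep("gazetteer", length(g_surface))),
    stringsAsFactors = FALSE)
  class(out) <- c("training_set", "data.frame")
  out
}

#' Stratified train/validation split by concept code
#'
#' For each code with n >= 2 mentions, `round(n * val_fraction)`
#' (half rounded up) go to validation, with at least one mention kept in
#' train; codes with a single mention stay entirely in train. Selection
#' within a code is a seeded uniform draw.
#'
#' @param mentions A `mention_set`; every mention must carry at least one
#'   code (the first code stratifies composite mentions).
#' @param val_fraction Validation fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return A list with `mention_set` elements `train` and `val`.
#' @export
stratified_split <- function(mentions, val_fraction, seed) {
  if (!is.numeric(val_fraction) || length(val_fraction) != 1 ||
      val_fraction <= 0 || val_fraction >= 1)
    stop_validation("val_fraction must lie strictly between 0 and 1")
  n_codes <- vapply(mentions$codes, length, integer(1))
  if (any(n_codes == 0))
    stop_validation("every mention must carry at least one code")
  strat <- vapply(mentions$codes, `[[`, character(1), 1L)
  val_idx <- integer(0)
  with_seed(seed, {
    for (code in sort(unique(strat))) {
      idx <- which(strat == code)
      n <- length(idx)
      if (n < 2) next
      n_val <- floor(n * val_fraction + 0.5)  # round half up
      n_val <- min(n_val, n - 1L)             # floor of 1 kept in train
      if (n_val > 0)
        val_idx <- c(val_idx, sample(idx, n_val))
    }
  })
  val_sel <- sort(val_idx)
  train <- mentions[setdiff(seq_len(nrow(mentions)), val_sel), , drop = FALSE]
  val <- mentions[val_sel, , drop = FALSE]
  rownames(train) <- NULL; rownames(val) <- NULL
  class(train) <- class(val) <- c("mention_set", "data.frame")
  list(train = train, val = val)
}
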