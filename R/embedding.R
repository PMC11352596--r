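# Embedding-backend contract plus the deterministic character n-gram
# hashing backend used for desk-scale testing. Any object with fields
# `dim` and `embed_batch(texts) -> matrix` can stand in for a transformer
# bi-encoder; the system never looks inside the backend.

#' Construct an embedding backend
#'
#' A backend is a list with a positive integer `dim` and a function
#' `embed_batch` mapping a character vector to a numeric matrix with one
#' row per input string. Backends must be deterministic within a process
#' and must never return an all-zero row for a non-empty input (they raise
#' instead).
#'
#' @param dim Embedding dimensionality.
#' @param embed_batch Function from character vector to numeric
#'   `length(texts) x dim` matrix.
#' @return An object of class `embedding_backend`.
#' @export
embedding_backend <- function(dim, embed_batch) {
  if (!is.numeric(dim) || length(dim) != 1 || dim < 1 || dim != round(dim))
    stop_validation("dim must be a positive integer")
  if (!is.function(embed_batch))
    stop_validation("embed_batch must be a function")
  structure(list(dim = as.integer(dim), embed_batch = embed_batch),
            class = "embedding_backend")
}

# Rolling polynomial hash of every character n-gram of one text.
# Returns a signed-count vector of length dim. p is a Mersenne prime;
# base stays small enough that all intermediates fit exactly in a double.
.hash_text_row <- function(text, dim, n_low, n_high, base, seed_mod, p) {
  b <- utf8ToInt(paste0("\u0001", tolower(text), "\u0002"))
  L <- length(b)
  pref <- numeric(L + 1)
  for (i in seq_len(L)) pref[i + 1] <- (pref[i] * base + b[i]) %% p
  idx <- integer(0); sgn <- integer(0)
  for (n in n_low:n_high) {
    if (L < n) next
    pw <- 1
    for (j in seq_len(n)) pw <- (pw * base) %% p
    starts <- seq_len(L - n + 1)
    h <- (pref[starts + n] - (pref[starts] * pw) %% p) %% p
    h <- (h * 31 + seed_mod) %% p  # mix the seed in after rolling
    idx <- c(idx, as.integer(h %% dim) + 1L)
    sgn <- c(sgn, 1L - 2L * as.integer((h %/% dim) %% 2))
  }
  tabulate(idx[sgn > 0], nbins = dim) - tabulate(idx[sgn < 0], nbins = dim)
}

#' Character n-gram hashing embedder
#'
#' Deterministic bag-of-character-n-grams embedding: each text is
#' lowercased, padded with boundary markers, decomposed into character
#' n-grams; each n-gram is hashed (seeded) to one of `dim` coordinates with
#' a pseudo-random sign, and rows are the signed n-gram counts. Identical
#' texts always produce identical rows.
#'
#' @param texts Character vector; empty strings are rejected.
#' @param dim Embedding dimensionality, at least 8.
#' @param n_range Integer pair `c(n_low, n_high)` with
#'   `1 <= n_low <= n_high <= 5`.
#' @param seed Integer hashing seed.
#' @return Numeric `length(texts) x dim` matrix.
#' @export
hash_ngram_embed <- function(texts, dim = 256L, n_range = c(2L, 4L),
                             seed = 13L) {
  if (dim < 8) stop_validation("dim must be at least 8")
  n_low <- as.integer(n_range[1]); n_high <- as.integer(n_range[2])
  if (n_low < 1 || n_high > 5 || n_low > n_high)
    stop_validation("n_range must satisfy 1 <= n_low <= n_high <= 5")
  if (any(!nzchar(texts)))
    stop_validation("cannot embed an empty string")
  p <- 67108859                         # largest prime < 2^26: p^2 < 2^53,
                                        # so modular products stay exact
  base <- 257 + abs(seed) %% 100
  seed_mod <- abs(seed) %% p
  out <- matrix(0, nrow = length(texts), ncol = dim)
  for (i in seq_along(texts)) {
    row <- .hash_text_row(texts[i], dim, n_low, n_high, base, seed_mod, p)
    if (all(row == 0))
      stop_format("hashing produced an all-zero row for '%s'", texts[i])
    out[i, ] <- row
  }
  out
}

#' Hashing backend with fixed parameters
#'
#' The shipped test backend: [hash_ngram_embed()] wrapped as an
#' `embedding_backend`. Defaults (dim 256, 2-4-grams, seed 13) separate
#' hundreds of synthetic concepts while staying cheap.
#'
#' @param dim,n_range,seed Passed to [hash_ngram_embed()].
#' @return An `embedding_backend`.
#' @export
hash_backend <- function(dim = 256L, n_range = c(2L, 4L), seed = 13L) {
  force(dim); force(n_range); force(seed)
  embedding_backend(dim, function(texts)
    hash_ngram_embed(texts, dim = dim, n_range = n_range, seed = seed))
}

#' Lookup backend over pre-computed (planted) vectors
#'
#' Returns a backend that maps each known surface string to a fixed
#' pre-computed row; unknown surfaces raise a validation error. Used by the
#' synthetic-data module so geometry is decoupled from any real embedder.
#'
#' @param surfaces Character vector of known surfaces.
#' @param vectors Numeric matrix, one row per surface.
#' @return An `embedding_backend`.
#' @export
lookup_backend <- function(surfaces, vectors) {
  vectors <- as.matrix(vectors)
  if (length(surfaces) != nrow(vectors))
    stop_validation("surfaces and vectors disagree in length")
  keep <- !duplicated(surfaces)
  surfaces <- surfaces[keep]
  vectors <- vectors[keep, , drop = FALSE]
  pos <- stats::setNames(seq_along(surfaces), surfaces)
  embedding_backend(ncol(vectors), function(texts) {
    i <- pos[texts]
    if (anyNA(i))
      stop_validation("lookup backend has no vector for '%s'",
                      texts[which(is.na(i))[1]])
    vectors[i, , drop = FALSE]
  })
}

#' L2-normalize a vector
#'
#' @param v Numeric vector with positive Euclidean norm.
#' @return The unit vector with the same direction.
#' @export
l2_normalize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (!is.finite(nrm) || nrm == 0)
    stop_validation("cannot l2-normalize a zero (or non-finite) vector")
  v / nrm
}

# Row-wise normalization; zero rows raise naming the offending row.
.l2_normalize_rows <- function(m, what = "row") {
  nrm <- sqrt(rowSums(m^2))
  bad <- which(nrm == 0 | !is.finite(nrm))
  if (length(bad) > 0)
    stop_validation("cannot l2-normalize zero %s %d", what, bad[1])
  m / nrm
}

#' Embed surfaces in batches
#'
#' Batch size is an implementation detail: the result is identical for any
#' `batch_size`. A backend failure is re-raised with the offending batch
#' index.
#'
#' @param backend An `embedding_backend`.
#' @param surfaces Non-empty character vector.
#' @param batch_size Positive integer.
#' @return Numeric `length(surfaces) x dim` matrix, rows aligned to input.
#' @export
embed_terms <- function(backend, surfaces, batch_size = 64L) {
  if (length(surfaces) == 0) stop_validation("surfaces must be non-empty")
  if (batch_size < 1) stop_validation("batch_size must be positive")
  starts <- seq(1L, length(surfaces), by = batch_size)
  rows <- vector("list", length(starts))
  for (bi in seq_along(starts)) {
    lo <- starts[bi]
    hi <- min(lo + batch_size - 1L, length(surfaces))
    rows[[bi]] <- tryCatch(
      backend$embed_batch(surfaces[lo:hi]),
      error = function(e) stop_training(
        "embedding backend failed on batch %d (surfaces %d-%d): %s",
        bi, lo, hi, conditionMessage(e)))
  }
  out <- do.call(rbind, rows)
  if (nrow(out) != length(surfaces) || ncol(out) != backend$dim)
    stop_format("backend returned a matrix of the wrong shape")
  dimnames(out) <- NULL
  out
}

#' Write / read an embedding matrix as plain text
#'
#' Format: first line `"n dim"`, then `n` whitespace-delimited rows printed
#' at 17 significant digits, which round-trips IEEE doubles exactly.
#'
#' @param m Numeric matrix.
#' @param path File path.
#' @return `read_embedding_matrix` returns the matrix; the writer returns
#'   the path invisibly.
#' @export
write_embedding_matrix <- function(m, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(apply(m, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_embedding_matrix
#' @export
read_embedding_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  if (length(hdr) != 2 || anyNA(hdr))
    stop_format("%s: malformed matrix header", path)
  if (length(lines) != hdr[1] + 1)
    stop_format("%s: expected %d data rows, found %d", path, hdr[1],
                length(lines) - 1)
  m <- matrix(0, nrow = hdr[1], ncol = hdr[2])
  for (i in seq_len(hdr[1])) {
    row <- as.numeric(strsplit(lines[i + 1], " ", fixed = TRUE)[[1]])
    if (length(row) != hdr[2]) stop_format("%s: ragged row %d", path, i)
    m[i, ] <- row
  }
  m
}
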