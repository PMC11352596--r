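# Independent oracles, deliberately written with plain loops and none of
# the package's ranking internals.

# Exhaustive cosine scan with per-code max pooling and the lexicographic
# tie-break, as a reference for retrieve()/predict_topk().
oracle_scan <- function(vectors, codes, query, k) {
  qn <- query / sqrt(sum(query^2))
  sims <- numeric(nrow(vectors))
  for (i in seq_len(nrow(vectors))) {
    v <- vectors[i, ]
    sims[i] <- sum(v * qn) / sqrt(sum(v^2))
  }
  ucodes <- unique(codes)
  best <- numeric(length(ucodes))
  for (j in seq_along(ucodes))
    best[j] <- max(sims[codes == ucodes[j]])
  ord <- order(-best, ucodes, method = "radix")
  take <- seq_len(min(k, length(ord)))
  data.frame(code = ucodes[ord[take]], score = best[ord[take]],
             stringsAsFactors = FALSE)
}

# Nearest-centroid-by-cosine classification, the tau-free equivalent of a
# freshly initialized head.
oracle_nearest_centroid <- function(centroids, codes, query) {
  qn <- query / sqrt(sum(query^2))
  best_code <- NA_character_
  best_sim <- -Inf
  for (i in seq_len(nrow(centroids))) {
    w <- centroids[i, ]
    s <- sum(w * qn) / sqrt(sum(w^2))
    if (s > best_sim || (s == best_sim && codes[i] < best_code)) {
      best_sim <- s
      best_code <- codes[i]
    }
  }
  best_code
}

# Direct cosine formula (no normalization helper).
oracle_cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# Shared small fixtures -------------------------------------------------

make_tiny_gazetteer <- function(path) {
  writeLines(c(
    "code\tlanguage\tterm\tsemantic_tag\tmainterm",
    "38341003\tes\thipertensión\tfinding\t1",
    "38341003\tes\ttensión alta\tfinding\t0",
    "25064002\tes\tcefalea\tfinding\t1",
    "49727002\tes\ttos\tfinding\t1"), path, useBytes = TRUE)
  path
}

make_tiny_annotations <- function(path, with_codes = TRUE) {
  hdr <- "filename\tlabel\tstart_span\tend_span\ttext"
  rows <- c("doc1\tSINTOMA\t10\t25\tdolor de cabeza",
            "doc1\tSINTOMA\t30\t33\ttos",
            "doc2\tSINTOMA\t0\t12\ttension alta")
  if (with_codes) {
    hdr <- paste0(hdr, "\tcode")
    rows <- paste0(rows, c("\t25064002", "\t49727002", "\t38341003"))
  }
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  path
}

# Helper: top-1 accuracy of a head on a matrix of query vectors.
head_top1 <- function(head, vectors, gold) {
  mean(vapply(seq_len(nrow(vectors)), function(i)
    predict_topk(head, vectors[i, ], 1)$code[1] == gold[i], logical(1)))
}

first_codes <- function(mentions)
  vapply(mentions$codes, `[[`, character(1), 1L)
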