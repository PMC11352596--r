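# Temperature-scaled cosine-softmax classification head over a frozen
# embedding backend. Per-concept weight rows are initialized as the mean
# (raw, un-normalized) embedding of every surface mapped to that concept;
# logits are cosines computed by normalizing both operands at call time,
# so the stored rows stay raw and the mean initialization is exact. The
# posterior over concepts is softmax(s / tau) with max-subtraction
# stabilization; tau concentrates or flattens the distribution.

#' Construct a concept-classification head
#'
#' @param weights Numeric `n_concepts x dim` matrix; row i is the weight
#'   vector of concept i (stored raw; normalized when logits are taken).
#' @param concept_order Character vector of distinct concept codes aligned
#'   to the rows of `weights`.
#' @param temperature Positive softmax temperature tau.
#' @return An object of class `wnt_head`.
#' @export
wnt_head <- function(weights, concept_order, temperature) {
  weights <- as.matrix(weights)
  if (nrow(weights) < 1) stop_validation("head needs at least one concept")
  if (length(concept_order) != nrow(weights))
    stop_validation("concept_order must align with weight rows")
  if (anyDuplicated(concept_order))
    stop_validation("concept_order must not contain duplicates")
  if (!all(is.finite(weights)))
    stop_validation("head weights must be finite")
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop_validation("temperature must be a positive real")
  structure(list(weights = weights,
                 concept_order = as.character(concept_order),
                 temperature = as.numeric(temperature)),
            class = "wnt_head")
}

#' @export
print.wnt_head <- function(x, ...) {
  cat(sprintf("wnt_head: %d concepts, dim %d, tau = %g\n",
              nrow(x$weights), ncol(x$weights), x$temperature))
  invisible(x)
}

#' Centroid initialization of the head
#'
#' Each concept's weight row starts as the arithmetic mean of the raw
#' embeddings of all training surfaces carrying that code (annotated
#' mentions and gazetteer terms alike). Concepts are ordered by sorted
#' code, and every code must have at least one entry.
#'
#' @param training_entries A `training_set` data frame (columns `surface`,
#'   `code`).
#' @param backend An `embedding_backend`.
#' @param temperature Softmax temperature; the 0.05 default follows the
#'   normalized-temperature-softmax lineage.
#' @param batch_size Embedding batch size.
#' @return A `wnt_head` whose `concept_order` is the sorted set of
#'   distinct codes.
#' @export
init_head <- function(training_entries, backend, temperature = 0.05,
                      batch_size = 64L) {
  if (nrow(training_entries) == 0)
    stop_validation("training set is empty")
  codes <- as.character(training_entries$code)
  emb <- embed_terms(backend, training_entries$surface, batch_size)
  concept_order <- sort(unique(codes), method = "radix")
  sums <- rowsum(emb, group = codes)           # rows ordered by sort(unique)
  counts <- as.integer(table(codes)[rownames(sums)])
  means <- sums / counts
  means <- means[concept_order, , drop = FALSE]
  zero <- which(rowSums(means != 0) == 0)
  if (length(zero) > 0)
    stop_training("mean embedding is the zero vector for concept %s",
                  concept_order[zero[1]])
  dimnames(means) <- NULL
  wnt_head(means, concept_order, temperature)
}

#' Cosine logits of a mention against every concept
#'
#' `s_i = cos(w_i, m)`: the dot product of the l2-normalized weight row and
#' the l2-normalized mention embedding. Invariant to positive rescaling of
#' either operand.
#'
#' @param head A `wnt_head`.
#' @param mention_vec Nonzero numeric vector of the head's dimensionality.
#' @return Numeric vector of cosines in `[-1, 1]`, aligned to
#'   `head$concept_order`.
#' @export
logits <- function(head, mention_vec) {
  m <- l2_normalize(as.numeric(mention_vec))
  w <- .l2_normalize_rows(head$weights, "weight row")
  s <- as.numeric(w %*% m)
  pmin(1, pmax(-1, s))
}

#' Posterior concept probabilities (temperature softmax)
#'
#' `p_i = exp(s_i / tau) / sum_j exp(s_j / tau)` computed with
#' max-subtraction stabilization. Small tau concentrates mass on the
#' argmax; large tau flattens the distribution.
#'
#' @inheritParams logits
#' @return Probability vector summing to one, aligned to
#'   `head$concept_order`.
#' @export
posterior <- function(head, mention_vec) {
  if (head$temperature <= 0) stop_validation("temperature must be positive")
  s <- logits(head, mention_vec) / head$temperature
  e <- exp(s - max(s))
  e / sum(e)
}

#' Rank concepts for a mention by posterior probability
#'
#' Equivalent to ranking by cosine logit (the softmax is monotone); ties
#' are broken lexicographically by code for deterministic output. Scores
#' reported are posteriors.
#'
#' @inheritParams logits
#' @param k Number of candidates to return (at most `n_concepts`).
#' @return A `candidate_list` data frame with columns `code`, `score`.
#' @export
predict_topk <- function(head, mention_vec, k) {
  if (k < 1) stop_validation("k must be at least 1")
  p <- posterior(head, mention_vec)
  ord <- order(-p, head$concept_order, method = "radix")
  take <- seq_len(min(k, length(ord)))
  out <- data.frame(code = head$concept_order[ord[take]],
                    score = p[ord[take]], stringsAsFactors = FALSE)
  class(out) <- c("candidate_list", "data.frame")
  out
}

#' Training configuration for head fine-tuning
#'
#' @param learning_rate Step size in `[0, 0.1]`; the bi-encoder literature
#'   this head targets uses 3e-5 to 5e-5. Zero is allowed (null update,
#'   useful as a control).
#' @param epochs Maximum number of passes over the data.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed driving the per-epoch shuffles.
#' @param patience Early stop after this many epochs without loss
#'   improvement; `Inf` disables early stopping.
#' @param optimizer `"adam"` (default) or `"sgd"`. Learning rates in the
#'   3e-5 range assume an adaptive optimizer; with plain gradient descent
#'   they produce numerically negligible updates, so SGD is kept only as a
#'   control.
#' @return A list of class `head_train_config`.
#' @export
head_train_config <- function(learning_rate = 3e-5, epochs = 20L,
                              batch_size = 32L, seed = 1L, patience = 3L,
                              optimizer = c("adam", "sgd")) {
  if (!is.numeric(learning_rate) || learning_rate < 0 || learning_rate > 0.1)
    stop_validation("learning_rate must lie in [0, 0.1]")
  if (epochs < 1) stop_validation("epochs must be positive")
  if (batch_size < 1) stop_validation("batch_size must be positive")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 patience = patience, optimizer = match.arg(optimizer)),
            class = "head_train_config")
}

# Forward pass for a batch of raw mention vectors (rows). Returns the
# posterior matrix, cosine matrix, and the normalized operands needed by
# the backward pass.
.head_forward <- function(W, X, tau) {
  w_norm <- sqrt(rowSums(W^2))
  Wn <- W / w_norm
  Xn <- X / sqrt(rowSums(X^2))
  S <- Xn %*% t(Wn)                     # b x n cosines
  Z <- S / tau
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(P = P, S = S, Wn = Wn, Xn = Xn, w_norm = w_norm)
}

#' Fine-tune the head weights over frozen mention embeddings
#'
#' Minimizes mean cross-entropy of the temperature-softmax posteriors by
#' mini-batch updates on the weight matrix only; the mention embeddings
#' are fixed inputs (the encoder stays frozen). The gradient passes
#' through the cosine normalization of each weight row. The default
#' optimizer is Adam (deterministic given the seed); plain gradient
#' descent is available as a control via the config. Shuffling is seeded
#' per epoch, so identical inputs and config reproduce bit-identical
#' weights.
#'
#' @param head A `wnt_head`.
#' @param mention_vecs Numeric matrix of raw mention embeddings, one row
#'   per training mention.
#' @param labels Character vector of gold codes, one per row; every label
#'   must be present in `head$concept_order`.
#' @param config A `head_train_config`.
#' @return A list with the updated `head` and `loss_trace`, the per-epoch
#'   mean cross-entropy (including epochs cut short by early stopping).
#' @export
finetune <- function(head, mention_vecs, labels, config = head_train_config()) {
  X <- as.matrix(mention_vecs)
  if (nrow(X) != length(labels))
    stop_validation("mention_vecs rows and labels disagree in length")
  lab_idx <- match(as.character(labels), head$concept_order)
  if (anyNA(lab_idx))
    stop_validation("label not in concept inventory: %s",
                    labels[which(is.na(lab_idx))[1]])
  W <- head$weights
  tau <- head$temperature
  lr <- config$learning_rate
  n <- nrow(W)
  loss_trace <- numeric(0)
  best_loss <- Inf
  stall <- 0L
  use_adam <- identical(config$optimizer %||% "adam", "adam")
  adam_m <- matrix(0, nrow(W), ncol(W))
  adam_v <- matrix(0, nrow(W), ncol(W))
  adam_t <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(nrow(X))
      starts <- seq(1L, nrow(X), by = config$batch_size)
      epoch_loss <- 0
      for (lo in starts) {
        hi <- min(lo + config$batch_size - 1L, nrow(X))
        rows <- perm[lo:hi]
        b <- length(rows)
        fw <- .head_forward(W, X[rows, , drop = FALSE], tau)
        yi <- lab_idx[rows]
        p_gold <- fw$P[cbind(seq_len(b), yi)]
        epoch_loss <- epoch_loss - sum(log(pmax(p_gold, 1e-300)))
        if (lr > 0) {
          G <- fw$P
          G[cbind(seq_len(b), yi)] <- G[cbind(seq_len(b), yi)] - 1
          G <- G / (tau * b)            # dL/dS, mean loss over the batch
          # dS/dW through row normalization:
          #   dL/dw_i = (G_i' Xn - (sum_b G_bi S_bi) wn_i) / ||w_i||
          A <- t(G) %*% fw$Xn
          cvec <- colSums(G * fw$S)
          dW <- (A - cvec * fw$Wn) / fw$w_norm
          if (use_adam) {
            adam_t <- adam_t + 1L
            adam_m <- beta1 * adam_m + (1 - beta1) * dW
            adam_v <- beta2 * adam_v + (1 - beta2) * dW^2
            m_hat <- adam_m / (1 - beta1^adam_t)
            v_hat <- adam_v / (1 - beta2^adam_t)
            W <- W - lr * m_hat / (sqrt(v_hat) + adam_eps)
          } else {
            W <- W - lr * dW
          }
          if (!all(is.finite(W)))
            stop_training("non-finite weights at epoch %d", epoch)
        }
      }
      epoch_loss <- epoch_loss / nrow(X)
      if (!is.finite(epoch_loss))
        stop_training("non-finite loss at epoch %d", epoch)
      loss_trace <- c(loss_trace, epoch_loss)
      if (epoch_loss < best_loss - 1e-12) {
        best_loss <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  list(head = wnt_head(W, head$concept_order, tau), loss_trace = loss_trace)
}

#' Serialize / deserialize a head
#'
#' Writes three sidecar text files: `<path>` (key=value header with the
#' temperature and shape), `<path>.mat` (the weight matrix in the package's
#' 17-significant-digit text format) and `<path>.codes` (one concept code
#' per line). The round-trip is exact.
#'
#' @param head A `wnt_head`.
#' @param path Base path for the three files.
#' @return `read_head` returns the `wnt_head`; the writer returns `path`
#'   invisibly.
#' @export
write_head <- function(head, path) {
  writeLines(c("format=wnt_head_v1",
               sprintf("tau=%.17g", head$temperature),
               sprintf("n_concepts=%d", nrow(head$weights)),
               sprintf("dim=%d", ncol(head$weights))),
             path, useBytes = TRUE)
  write_embedding_matrix(head$weights, paste0(path, ".mat"))
  writeLines(head$concept_order, paste0(path, ".codes"), useBytes = TRUE)
  invisible(path)
}

#' @rdname write_head
#' @export
read_head <- function(path) {
  hdr <- readLines(path, encoding = "UTF-8")
  kv <- strsplit(hdr, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  if (is.na(vals["format"]) || vals["format"] != "wnt_head_v1")
    stop_format("%s: not a serialized head", path)
  W <- read_embedding_matrix(paste0(path, ".mat"))
  codes <- readLines(paste0(path, ".codes"), encoding = "UTF-8")
  wnt_head(W, codes, as.numeric(vals["tau"]))
}
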