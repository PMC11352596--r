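test_that("init_head averages raw embeddings per sorted concept", {
  # 5 concepts x 3 terms with a planted lookup backend
  set.seed(31)
  codes <- rep(sprintf("c%d", 5:1), each = 3)       # unsorted input order
  surfaces <- sprintf("s%02d", seq_along(codes))
  vec <- matrix(stats::rnorm(length(codes) * 8), ncol = 8)
  be <- lookup_backend(surfaces, vec)
  ts <- data.frame(surface = surfaces, code = codes, source = "gazetteer",
                   stringsAsFactors = FALSE)
  head <- init_head(ts, be, temperature = 0.05)
  expect_identical(head$concept_order, sort(unique(codes)))
  for (cc in unique(codes)) {
    rows <- which(codes == cc)
    want <- colMeans(vec[rows, , drop = FALSE])     # independent column mean
    expect_equal(head$weights[match(cc, head$concept_order), ], want,
                 tolerance = 1e-12)
  }
  # single-term concept: row equals the embedding exactly
  ts1 <- ts[1, , drop = FALSE]
  h1 <- init_head(ts1, be)
  expect_identical(h1$weights[1, ], vec[1, ])
  # symmetry example: (1,0) and (0,1) average to (0.5, 0.5)
  be2 <- lookup_backend(c("a", "b"), rbind(c(1, 0), c(0, 1)))
  h2 <- init_head(data.frame(surface = c("a", "b"), code = "c",
                             stringsAsFactors = FALSE), be2)
  expect_equal(h2$weights[1, ], c(0.5, 0.5))
  # zero mean embedding is an error naming the code
  be3 <- lookup_backend(c("a", "b"), rbind(c(1, 1), c(-1, -1)))
  expect_error(init_head(data.frame(surface = c("a", "b"), code = "cz",
                                    stringsAsFactors = FALSE), be3),
               "cz", class = "wntlink_training_error")
})

test_that("logits are cosines: orthonormal, scale-invariant, hand value", {
  h <- wnt_head(rbind(c(1, 0), c(0, 1)), c("a", "b"), 1)
  expect_equal(logits(h, c(1, 0)), c(1, 0))
  expect_equal(logits(h, c(2, 0)), c(1, 0))           # scale invariance
  h2 <- wnt_head(rbind(c(1, 1)), "a", 1)
  expect_equal(logits(h2, c(1, 0)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(logits(h, c(0, 0)), class = "wntlink_validation_error")
})

test_that("posterior is a stabilized temperature softmax", {
  h <- wnt_head(rbind(c(1, 0), c(0, 1)), c("a", "b"), 1)
  p <- posterior(h, c(1, 0))                          # s = (1, 0), tau = 1
  expect_equal(p, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(p, c(0.73106, 0.26894), tolerance = 1e-5)
  # sharpening: tau = 0.05 -> p2 = 1 / (1 + e^20)
  h05 <- wnt_head(rbind(c(1, 0), c(0, 1)), c("a", "b"), 0.05)
  p05 <- posterior(h05, c(1, 0))
  expect_gte(p05[1], 1 - 1e-8)
  expect_equal(p05[2], 1 / (1 + exp(20)), tolerance = 1e-12)
  # n = 1 normalizes to 1 for any tau
  expect_equal(posterior(wnt_head(rbind(c(1, 1)), "a", 7), c(3, 1)), 1)
  expect_error(wnt_head(rbind(c(1, 0)), "a", -1),
               class = "wntlink_validation_error")
})

test_that("posterior properties: normalization, positivity, scale and tau", {
  set.seed(41)
  for (r in 1:20) {
    n <- sample(2:30, 1)
    dim <- sample(4:16, 1)
    h <- wnt_head(matrix(stats::rnorm(n * dim), n),
                  sprintf("c%02d", 1:n), stats::runif(1, 0.01, 5))
    m <- stats::rnorm(dim)
    p <- posterior(h, m)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p > 0))
    # cosine contract: positive rescaling of the query changes nothing
    expect_equal(posterior(h, 3.7 * m), p, tolerance = 1e-12)
  }
  # temperature limit on fixed logits: tau 1e-3 vs tau 1 concentrates
  # the mass on the argmax (orthonormal rows give a known cosine gap)
  W <- diag(5)
  m <- c(1, 0.8, 0.3, 0.1, 0)
  h1 <- wnt_head(W, sprintf("c%d", 1:5), 1)
  h_cold <- wnt_head(W, sprintf("c%d", 1:5), 1e-3)
  expect_gt(max(posterior(h_cold, m)), max(posterior(h1, m)))
  expect_gt(max(posterior(h_cold, m)), 1 - 1e-6)
})

test_that("predict_topk ranks by posterior with lexicographic ties", {
  set.seed(43)
  h <- wnt_head(matrix(stats::rnorm(10 * 8), 10), sprintf("c%02d", 1:10),
                0.05)
  m <- stats::rnorm(8)
  top <- predict_topk(h, m, 3)
  expect_equal(top$code[1], h$concept_order[which.max(logits(h, m))])
  expect_setequal(predict_topk(h, m, 10)$code, h$concept_order)
  # duplicated weight rows tie exactly; lexicographically smaller code wins
  ht <- wnt_head(rbind(c(1, 0), c(1, 0), c(0, 1)), c("b", "a", "z"), 0.05)
  expect_equal(predict_topk(ht, c(1, 0), 2)$code, c("a", "b"))
})

test_that("fresh-init predict_topk equals nearest-centroid oracle", {
  set.seed(47)
  for (r in 1:5) {
    n <- 30; dim <- 16
    codes <- sprintf("c%02d", 1:n)
    surf <- sprintf("s%02d", 1:n)
    vec <- matrix(stats::rnorm(n * dim), n)
    head <- init_head(data.frame(surface = surf, code = codes,
                                 stringsAsFactors = FALSE),
                      lookup_backend(surf, vec),
                      temperature = stats::runif(1, 0.01, 2))
    for (q in 1:20) {
      m <- stats::rnorm(dim)
      expect_equal(predict_topk(head, m, 1)$code,
                   oracle_nearest_centroid(head$weights,
                                           head$concept_order, m))
    }
  }
})

test_that("finetune: null update, descent, determinism, validation", {
  set.seed(53)
  n <- 3; dim <- 8
  centers <- matrix(stats::rnorm(n * dim), n)
  centers <- centers / sqrt(rowSums(centers^2))
  X <- centers[rep(1:n, each = 30), ] +
    matrix(stats::rnorm(90 * dim, sd = 0.05), 90)
  labels <- rep(c("a", "b", "c"), each = 30)
  h0 <- wnt_head(centers + stats::rnorm(n * dim, sd = 0.3),
                 c("a", "b", "c"), 0.05)

  # learning rate zero: weights unchanged, constant loss trace
  fit0 <- finetune(h0, X, labels,
                   head_train_config(learning_rate = 0, epochs = 5,
                                     seed = 1, patience = Inf))
  expect_identical(fit0$head$weights, h0$weights)
  expect_equal(diff(fit0$loss_trace), rep(0, 4), tolerance = 1e-12)

  # descent on separable clusters
  fit <- finetune(h0, X, labels,
                  head_train_config(learning_rate = 3e-4, epochs = 50,
                                    seed = 1, patience = Inf))
  expect_lt(utils::tail(fit$loss_trace, 1), fit$loss_trace[1])

  # bit-identical reruns
  fit2 <- finetune(h0, X, labels,
                   head_train_config(learning_rate = 3e-4, epochs = 50,
                                     seed = 1, patience = Inf))
  expect_identical(fit$head$weights, fit2$head$weights)

  expect_error(finetune(h0, X, rep("zz", nrow(X)), head_train_config()),
               "zz", class = "wntlink_validation_error")
})

test_that("sgd gradient matches a numerical gradient of the objective", {
  set.seed(59)
  n <- 3; dim <- 5; tau <- 0.05
  W <- matrix(stats::rnorm(n * dim), n)
  X <- matrix(stats::rnorm(4 * dim), 4)
  labels <- c("c1", "c2", "c3", "c1")
  h0 <- wnt_head(W, c("c1", "c2", "c3"), tau)
  lr <- 1e-6
  fit <- finetune(h0, X, labels,
                  head_train_config(learning_rate = lr, epochs = 1,
                                    batch_size = 4, seed = 1,
                                    optimizer = "sgd"))
  implied <- (W - fit$head$weights) / lr
  loss_at <- function(Wp) {
    h <- wnt_head(Wp, c("c1", "c2", "c3"), tau)
    mean(vapply(seq_len(nrow(X)), function(i)
      -log(posterior(h, X[i, ])[match(labels[i], h$concept_order)]),
      numeric(1)))
  }
  numgrad <- matrix(0, n, dim)
  eps <- 1e-6
  for (i in seq_len(n)) for (j in seq_len(dim)) {
    e <- matrix(0, n, dim); e[i, j] <- eps
    numgrad[i, j] <- (loss_at(W + e) - loss_at(W - e)) / (2 * eps)
  }
  expect_equal(implied, numgrad, tolerance = 1e-5)
})

test_that("head serialization round-trips exactly", {
  set.seed(61)
  h <- wnt_head(matrix(stats::rnorm(6 * 4), 6), sprintf("c%d", 1:6), 0.05)
  path <- withr::local_tempfile()
  write_head(h, path)
  h2 <- read_head(path)
  expect_identical(h2$weights, h$weights)
  expect_identical(h2$concept_order, h$concept_order)
  expect_identical(h2$temperature, h$temperature)
})
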