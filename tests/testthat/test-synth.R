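# Smaller-than-default configs keep the module tests fast; the full
# default scenario runs once in test-acceptance.R.
small_cfg <- function(...) synth_config(n_concepts = 40L, dim = 32L,
                                        mentions_per_concept_train = 5L,
                                        mentions_per_concept_val = 2L,
                                        mentions_per_concept_test = 5L, ...)

test_that("generate_geometry is seeded, unit-norm and near-orthogonal", {
  cfg <- synth_config(n_concepts = 100L, dim = 64L, seed = 5)
  g1 <- generate_geometry(cfg)
  g2 <- generate_geometry(cfg)
  expect_identical(g1, g2)
  expect_equal(sqrt(rowSums(g1$latent^2)), rep(1, 100), tolerance = 1e-9)
  expect_false(anyDuplicated(g1$codes) > 0)
  expect_equal(unique(g1$tags[1:3]),
               c("finding", "disorder", "morphologic abnormality"))
  gram <- g1$latent %*% t(g1$latent)
  offdiag <- abs(gram[upper.tri(gram)])
  # high-dimensional near-orthogonality: E|cos| = sqrt(2 / (pi * dim))
  # (= 0.0997 at dim 64, so a raw "< 0.1" band would fail ~half of all
  # seeds by construction); check the empirical mean against the exact
  # expectation instead
  expect_equal(mean(offdiag), sqrt(2 / (pi * 64)), tolerance = 0.05)
  expect_lt(mean(offdiag), 0.105)
})

test_that("generate_gazetteer plants synonyms around the latent", {
  cfg <- small_cfg(seed = 9)
  geo <- generate_geometry(cfg)
  gz <- generate_gazetteer(geo, cfg)
  expect_s3_class(gz$entries, "gazetteer")
  expect_equal(nrow(gz$entries), nrow(gz$vectors))
  expect_true(all(gz$entries$code %in% geo$codes))
  # every concept has >= 1 synonym, the first flagged as main term
  expect_setequal(unique(gz$entries$code), geo$codes)
  expect_true(all(tapply(gz$entries$is_main_term, gz$entries$code, sum) == 1))

  # zero term noise: synonym vectors equal their concept latent
  cfg0 <- small_cfg(term_noise_sd = 0, seed = 9)
  gz0 <- generate_gazetteer(generate_geometry(cfg0), cfg0)
  i <- match(gz0$entries$code, generate_geometry(cfg0)$codes)
  expect_equal(gz0$vectors, generate_geometry(cfg0)$latent[i, ],
               tolerance = 1e-12)
})

test_that("synonym counts match the shifted-Poisson mean", {
  cfg <- synth_config(n_concepts = 200L, dim = 16L, mean_synonyms = 3,
                      seed = 21)
  gz <- generate_gazetteer(generate_geometry(cfg), cfg)
  total <- nrow(gz$entries)
  expect_lt(abs(total - 200 * 3), 3 * sqrt(200 * 3))
})

test_that("generate_mentions is deterministic with planted vectors", {
  cfg <- small_cfg(seed = 11)
  geo <- generate_geometry(cfg)
  m1 <- generate_mentions(geo, cfg, "train")
  m2 <- generate_mentions(geo, cfg, "train")
  expect_identical(m1, m2)
  expect_equal(nrow(m1$mentions), 40 * 5)
  expect_equal(nrow(m1$mentions), nrow(m1$vectors))
  # the mention-set invariant: text length equals end - start
  expect_equal(nchar(m1$mentions$text),
               m1$mentions$end - m1$mentions$start)

  # noiseless world: nearest centroid classifies test mentions perfectly
  cfg0 <- small_cfg(term_noise_sd = 0, mention_noise_sd = 0, seed = 11)
  geo0 <- generate_geometry(cfg0)
  te <- generate_mentions(geo0, cfg0, "test")
  pred <- vapply(seq_len(nrow(te$vectors)), function(i)
    oracle_nearest_centroid(geo0$latent, geo0$codes, te$vectors[i, ]),
    character(1))
  expect_equal(pred, first_codes(te$mentions))
})

test_that("zero-shot fraction lands a binomial share of test mentions", {
  cfg <- synth_config(n_concepts = 200L, dim = 16L,
                      mentions_per_concept_test = 5L,
                      zero_shot_fraction = 0.1, seed = 31)
  geo <- generate_geometry(cfg)
  te <- generate_mentions(geo, cfg, "test")     # 1000 test mentions
  n_zs <- sum(!(first_codes(te$mentions) %in% geo$codes))
  expect_equal(nrow(te$mentions), 1000)
  expect_lt(abs(n_zs - 100), 40)                # ~4 binomial SDs
  expect_true(all(first_codes(te$mentions)[!(first_codes(te$mentions)
              %in% geo$codes)] %in% geo$reserve_codes))
  # train split never touches the reserve pool
  tr <- generate_mentions(geo, cfg, "train")
  expect_true(all(first_codes(tr$mentions) %in% geo$codes))
})

test_that("mention noise degrades initialized-head accuracy monotonically", {
  accs <- vapply(c(0.2, 0.6, 1.0), function(sd) {
    mean(vapply(1:2, function(s) {
      cfg <- small_cfg(mention_noise_sd = sd, seed = s)
      sc <- recovery_scenario(cfg)
      h0 <- init_head(sc$training_set, sc$backend)
      head_top1(h0, sc$val_vectors, first_codes(sc$val))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) < 0))
})

test_that("generate_ner_corpus offsets slice to the surface; members err", {
  cfg <- small_cfg(seed = 13)
  ner <- generate_ner_corpus(cfg, n_docs = 10, n_members = 3,
                             miss_rate = 0, false_alarm_rate = 0)
  doc_text <- stats::setNames(ner$documents$text, ner$documents$doc_id)
  for (i in seq_len(nrow(ner$gold))) {
    g <- ner$gold[i, ]
    expect_identical(substr(doc_text[[g$doc_id]], g$start + 1, g$end),
                     g$text)
  }
  # noiseless members equal gold, and voting returns gold
  key <- wntlink:::.span_key
  for (m in ner$member_predictions)
    expect_setequal(key(m), key(ner$gold))
  expect_setequal(key(majority_vote(ner$member_predictions)),
                  key(ner$gold))

  # miss rate shows up as member recall ~ 0.7
  ner2 <- generate_ner_corpus(small_cfg(seed = 17), n_docs = 25,
                              n_members = 4, miss_rate = 0.3,
                              false_alarm_rate = 0)
  recalls <- vapply(ner2$member_predictions, function(m)
    ner_prf(ner2$gold, m)$recall, numeric(1))
  expect_lt(abs(mean(recalls) - 0.7), 0.1)
})

test_that("recovery_scenario wires the lookup backend consistently", {
  cfg <- small_cfg(seed = 19)
  sc <- recovery_scenario(cfg, with_test = TRUE)
  expect_equal(nrow(sc$training_set),
               nrow(sc$train) + nrow(sc$gazetteer$entries))
  expect_equal(nrow(sc$training_vectors), nrow(sc$training_set))
  # backend returns the planted vectors for enriched training surfaces
  got <- sc$backend$embed_batch(sc$training_set$surface[1:5])
  expect_equal(got, sc$training_vectors[1:5, , drop = FALSE])
  # and for raw validation texts
  gotv <- sc$backend$embed_batch(sc$val$text[1:3])
  expect_equal(gotv, sc$val_vectors[1:3, , drop = FALSE])
})

test_that("write_scenario emits loadable files in the package dialects", {
  dir <- withr::local_tempdir()
  write_scenario(small_cfg(seed = 23), dir)
  g <- load_gazetteer(file.path(dir, "gazetteer.tsv"))
  expect_gt(nrow(g), 0)
  tr <- load_annotations(file.path(dir, "train.tsv"))
  expect_equal(nrow(tr), 40 * 5)
  vec <- read_embedding_matrix(file.path(dir, "train_vectors.txt"))
  expect_equal(nrow(vec), nrow(tr))
  gold <- load_annotations(file.path(dir, "ner_gold.tsv"),
                           with_codes = FALSE)
  expect_gt(nrow(gold), 0)
})
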