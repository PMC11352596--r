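# Synthetic world generator. Emulates the statistical structure the
# linking method assumes: a gazetteer with several synonyms per concept, a
# latent unit direction per concept in embedding space, term and mention
# embeddings scattered around their concept direction with Gaussian noise,
# scarce annotated mentions, an optional zero-shot fraction of test
# mentions whose concepts are absent from the gazetteer, and a template
# NER corpus with noisy ensemble-member predictions. Tests run against a
# lookup backend returning the planted vectors, which decouples the
# geometry from any real embedder.

#' Synthetic-scenario configuration
#'
#' Defaults are the package's standard recovery scenario: 200 concepts in
#' 64 dimensions, a shifted-Poisson synonym count with mean 3, term noise
#' 0.3 and mention noise 0.6 (mentions are harder than gazetteer terms),
#' 20 training and 5 validation mentions per concept, no zero-shot
#' mentions.
#'
#' @param n_concepts Number of concepts (>= 2).
#' @param dim Embedding dimensionality (>= 8).
#' @param mean_synonyms Mean synonyms per concept; counts are drawn as
#'   `1 + Poisson(mean_synonyms - 1)`.
#' @param mentions_per_concept_train,mentions_per_concept_val,mentions_per_concept_test
#'   Mentions drawn per concept in each split.
#' @param term_noise_sd,mention_noise_sd Gaussian perturbation SDs applied
#'   to the concept direction before re-normalization.
#' @param zero_shot_fraction Fraction of TEST mentions whose gold concept
#'   is drawn from a reserve pool absent from the gazetteer; in `[0, 1)`.
#' @param tag_set Semantic tags assigned round-robin to concepts.
#' @param seed Master seed; each generator derives its own stream from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_concepts = 200L, dim = 64L, mean_synonyms = 3,
                         mentions_per_concept_train = 20L,
                         mentions_per_concept_val = 5L,
                         mentions_per_concept_test = 5L,
                         term_noise_sd = 0.3, mention_noise_sd = 0.6,
                         zero_shot_fraction = 0,
                         tag_set = c("finding", "disorder",
                                     "morphologic abnormality"),
                         seed = 1L) {
  if (n_concepts < 2) stop_validation("n_concepts must be at least 2")
  if (dim < 8) stop_validation("dim must be at least 8")
  if (mean_synonyms < 1) stop_validation("mean_synonyms must be >= 1")
  if (term_noise_sd < 0 || mention_noise_sd < 0)
    stop_validation("noise SDs must be non-negative")
  if (zero_shot_fraction < 0 || zero_shot_fraction >= 1)
    stop_validation("zero_shot_fraction must lie in [0, 1)")
  structure(list(n_concepts = as.integer(n_concepts), dim = as.integer(dim),
                 mean_synonyms = mean_synonyms,
                 mentions_per_concept_train = as.integer(mentions_per_concept_train),
                 mentions_per_concept_val = as.integer(mentions_per_concept_val),
                 mentions_per_concept_test = as.integer(mentions_per_concept_test),
                 term_noise_sd = term_noise_sd,
                 mention_noise_sd = mention_noise_sd,
                 zero_shot_fraction = zero_shot_fraction,
                 tag_set = tag_set, seed = as.integer(seed)),
            class = "synth_config")
}

.unit_rows <- function(n, dim) {
  m <- matrix(stats::rnorm(n * dim), nrow = n)
  .l2_normalize_rows(m)
}

#' Draw the latent concept geometry
#'
#' One independent uniform unit direction per concept, plus a reserve pool
#' of extra concepts (codes prefixed differently) used only for zero-shot
#' test mentions. Tags are assigned round-robin from the tag set.
#'
#' @param config A `synth_config`.
#' @return A list of class `concept_geometry` with `latent` (unit-row
#'   matrix), `codes`, `tags`, and `reserve_latent` / `reserve_codes` for
#'   the zero-shot pool.
#' @export
generate_geometry <- function(config) {
  n <- config$n_concepts
  n_res <- max(2L, ceiling(0.1 * n))
  with_seed(config$seed, {
    latent <- .unit_rows(n, config$dim)
    reserve <- .unit_rows(n_res, config$dim)
  })
  structure(list(
    latent = latent,
    codes = sprintf("8%06d", seq_len(n)),
    tags = rep_len(config$tag_set, n),
    reserve_latent = reserve,
    reserve_codes = sprintf("9%06d", seq_len(n_res))),
    class = "concept_geometry")
}

#' Generate a synthetic gazetteer with planted term embeddings
#'
#' Each concept receives `1 + Poisson(mean_synonyms - 1)` synonym surfaces
#' (synthetic strings encoding concept and synonym ids); each synonym's
#' planted embedding is the l2-normalized sum of the concept direction and
#' `term_noise_sd` Gaussian noise. The planted vectors are returned so
#' callers can build a [lookup_backend()].
#'
#' @param geometry A `concept_geometry`.
#' @param config The `synth_config` used to build it.
#' @return A list with `entries` (a `gazetteer`) and `vectors` (matrix
#'   aligned to entries).
#' @export
generate_gazetteer <- function(geometry, config) {
  n <- config$n_concepts
  with_seed(config$seed + 1L, {
    counts <- 1L + stats::rpois(n, config$mean_synonyms - 1)
    rows <- vector("list", n)
    vecs <- vector("list", n)
    for (i in seq_len(n)) {
      j <- seq_len(counts[i])
      rows[[i]] <- data.frame(
        code = geometry$codes[i],
        term = sprintf("termino %s sin%02d", geometry$codes[i], j),
        semantic_tag = geometry$tags[i],
        language = "es",
        is_main_term = j == 1L,
        stringsAsFactors = FALSE)
      noise <- matrix(stats::rnorm(counts[i] * config$dim),
                      nrow = counts[i]) * config$term_noise_sd
      base <- matrix(geometry$latent[i, ], nrow = counts[i],
                     ncol = config$dim, byrow = TRUE)
      vecs[[i]] <- .l2_normalize_rows(base + noise)
    }
  })
  entries <- do.call(rbind, rows)
  class(entries) <- c("gazetteer", "data.frame")
  list(entries = entries, vectors = do.call(rbind, vecs))
}

#' Generate synthetic annotated mentions with planted embeddings
#'
#' Draws `mentions_per_concept_<split>` mentions per concept; each
#' mention's planted embedding is the l2-normalized sum of its concept
#' direction and `mention_noise_sd` Gaussian noise. For the test split, a
#' `zero_shot_fraction` of mentions independently swap their concept for a
#' reserve-pool concept absent from the gazetteer.
#'
#' @param geometry A `concept_geometry`.
#' @param config The matching `synth_config`.
#' @param split One of `"train"`, `"val"`, `"test"`.
#' @return A list with `mentions` (a `mention_set`) and `vectors` (matrix
#'   aligned to mentions).
#' @export
generate_mentions <- function(geometry, config,
                              split = c("train", "val", "test")) {
  split <- match.arg(split)
  per <- switch(split,
                train = config$mentions_per_concept_train,
                val = config$mentions_per_concept_val,
                test = config$mentions_per_concept_test)
  if (per < 1) stop_validation("mentions per concept must be >= 1")
  offset <- switch(split, train = 2L, val = 3L, test = 4L)
  n <- config$n_concepts
  concept <- rep(seq_len(n), each = per)
  total <- length(concept)
  with_seed(config$seed + offset, {
    is_zs <- if (split == "test" && config$zero_shot_fraction > 0)
      stats::runif(total) < config$zero_shot_fraction
    else rep(FALSE, total)
    zs_pick <- sample.int(nrow(geometry$reserve_latent), total,
                          replace = TRUE)
    noise <- matrix(stats::rnorm(total * config$dim), nrow = total) *
      config$mention_noise_sd
  })
  base <- geometry$latent[concept, , drop = FALSE]
  codes <- geometry$codes[concept]
  base[is_zs, ] <- geometry$reserve_latent[zs_pick[is_zs], , drop = FALSE]
  codes[is_zs] <- geometry$reserve_codes[zs_pick[is_zs]]
  vectors <- .l2_normalize_rows(base + noise)
  text <- sprintf("mencion %s %s%03d", codes, split,
                  stats::ave(seq_len(total), codes, FUN = seq_along))
  mentions <- data.frame(
    doc_id = sprintf("synthdoc_%s", split),
    label = "SINTOMA",
    start = 0L, end = nchar(text), text = text,
    stringsAsFactors = FALSE)
  mentions$codes <- as.list(codes)
  class(mentions) <- c("mention_set", "data.frame")
  list(mentions = mentions, vectors = vectors)
}

#' Generate a template NER corpus with noisy ensemble members
#'
#' Builds documents of template sentences with an embedded mention surface
#' at a known offset, the gold span set, and `n_members` synthetic member
#' predictions derived from gold by independent seeded span deletion
#' (`miss_rate`) and spurious-span insertion (`false_alarm_rate` expected
#' spurious spans per gold span, placed on random non-gold tokens).
#'
#' @param config A `synth_config` (only `seed` is used for randomness).
#' @param n_docs Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param n_members Number of ensemble members to simulate.
#' @param miss_rate Per-span deletion probability for each member.
#' @param false_alarm_rate Expected spurious spans per gold span.
#' @return A list with `documents` (data frame `doc_id`, `text`), `gold`
#'   (a `span_set` that also carries the mention `text`), and
#'   `member_predictions` (list of `span_set`).
#' @export
generate_ner_corpus <- function(config, n_docs = 20L, sentences_per_doc = 4L,
                                n_members = 5L, miss_rate = 0.2,
                                false_alarm_rate = 0.2) {
  if (miss_rate < 0 || miss_rate >= 1 || false_alarm_rate < 0)
    stop_validation("invalid miss/false-alarm rates")
  openers <- c("El paciente presenta", "Se observa", "Refiere",
               "La exploracion revela")
  closers <- c("desde ayer.", "sin fiebre.", "de forma aguda.",
               "en seguimiento.")
  docs <- vector("list", n_docs)
  gold <- list()
  with_seed(config$seed + 5L, {
    for (d in seq_len(n_docs)) {
      doc_id <- sprintf("nerdoc%03d", d)
      pieces <- character(sentences_per_doc)
      pos <- 0L
      for (s in seq_len(sentences_per_doc)) {
        surface <- sprintf("sintoma %03d",
                           sample.int(3L * n_docs, 1L))
        opener <- sample(openers, 1L)
        closer <- sample(closers, 1L)
        sent <- paste(opener, surface, closer)
        m_start <- pos + nchar(opener) + 1L
        gold[[length(gold) + 1]] <- data.frame(
          doc_id = doc_id, start = m_start,
          end = m_start + nchar(surface), label = "SINTOMA",
          text = surface, stringsAsFactors = FALSE)
        pieces[s] <- sent
        pos <- pos + nchar(sent) + 1L   # sentences joined by one space
      }
      docs[[d]] <- data.frame(doc_id = doc_id,
                              text = paste(pieces, collapse = " "),
                              stringsAsFactors = FALSE)
    }
    documents <- do.call(rbind, docs)
    gold <- do.call(rbind, gold)
    class(gold) <- c("span_set", "data.frame")
    members <- vector("list", n_members)
    for (m in seq_len(n_members)) {
      keep <- stats::runif(nrow(gold)) >= miss_rate
      pred <- gold[keep, c("doc_id", "start", "end", "label"), drop = FALSE]
      n_spur <- stats::rbinom(1L, nrow(gold), min(false_alarm_rate, 1))
      if (n_spur > 0) {
        spur <- vector("list", n_spur)
        for (q in seq_len(n_spur)) {
          di <- sample.int(nrow(documents), 1L)
          toks <- whitespace_tokenizer()(documents$text[di])
          ti <- sample.int(nrow(toks), 1L)
          spur[[q]] <- data.frame(doc_id = documents$doc_id[di],
                                  start = toks$start[ti], end = toks$end[ti],
                                  label = "SINTOMA", stringsAsFactors = FALSE)
        }
        spur <- do.call(rbind, spur)
        # spurious spans must not coincide with a gold span
        spur <- spur[!(.span_key(spur) %in% .span_key(gold)), , drop = FALSE]
        pred <- rbind(pred, spur)
      }
      pred <- pred[!duplicated(.span_key(pred)), , drop = FALSE]
      rownames(pred) <- NULL
      class(pred) <- c("span_set", "data.frame")
      members[[m]] <- pred
    }
  })
  list(documents = documents, gold = gold, member_predictions = members)
}

#' Assemble the standard recovery scenario
#'
#' Glues the generators together into everything a linking experiment
#' needs: geometry, gazetteer, train/val (and optionally test) mentions,
#' the concatenated training set (mention surfaces first, then gazetteer
#' entries, all tag-enriched), embedding matrices aligned to the training
#' set, and a planted-vector [lookup_backend()] that knows every surface
#' in play (tag-enriched training surfaces and raw mention texts for
#' inference-time queries).
#'
#' @param config A `synth_config`.
#' @param with_test Also generate the test split.
#' @return A list with components `config`, `geometry`, `gazetteer`
#'   (entries + vectors), `train`, `val` (and `test`) mention sets with
#'   aligned `*_vectors`, `training_set`, `training_vectors`, and
#'   `backend`.
#' @export
recovery_scenario <- function(config = synth_config(), with_test = FALSE) {
  geometry <- generate_geometry(config)
  gaz <- generate_gazetteer(geometry, config)
  tr <- generate_mentions(geometry, config, "train")
  va <- generate_mentions(geometry, config, "val")
  te <- if (with_test) generate_mentions(geometry, config, "test")
  tag_lookup <- stats::setNames(geometry$tags, geometry$codes)
  training_set <- build_training_set(tr$mentions, gaz$entries, tag_lookup)
  training_vectors <- rbind(tr$vectors, gaz$vectors)
  # register every surface the pipeline may embed: enriched training
  # surfaces plus raw mention texts (queries carry no tag at inference)
  surfaces <- c(training_set$surface, tr$mentions$text, va$mentions$text,
                gaz$entries$term)
  vectors <- rbind(training_vectors, tr$vectors, va$vectors, gaz$vectors)
  if (with_test) {
    surfaces <- c(surfaces, te$mentions$text)
    vectors <- rbind(vectors, te$vectors)
  }
  backend <- lookup_backend(surfaces, vectors)
  out <- list(config = config, geometry = geometry, gazetteer = gaz,
              train = tr$mentions, train_vectors = tr$vectors,
              val = va$mentions, val_vectors = va$vectors,
              training_set = training_set,
              training_vectors = training_vectors,
              backend = backend)
  if (with_test) {
    out$test <- te$mentions
    out$test_vectors <- te$vectors
  }
  out
}

#' Write a full synthetic scenario to disk in the package dialects
#'
#' Emits the gazetteer TSV, one annotation TSV per split, the planted
#' vector matrices, and the NER fixture files, so the command-line tools
#' can be exercised end to end without any external corpus.
#'
#' @param config A `synth_config`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_scenario <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sc <- recovery_scenario(config, with_test = TRUE)
  write_gazetteer(sc$gazetteer$entries, file.path(dir, "gazetteer.tsv"))
  for (split in c("train", "val", "test")) {
    write_annotations(sc[[split]], file.path(dir, paste0(split, ".tsv")))
    write_embedding_matrix(sc[[paste0(split, "_vectors")]],
                           file.path(dir, paste0(split, "_vectors.txt")))
  }
  write_embedding_matrix(sc$gazetteer$vectors,
                         file.path(dir, "gazetteer_vectors.txt"))
  ner <- generate_ner_corpus(config)
  utils::write.table(ner$documents, file.path(dir, "ner_documents.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  gold <- ner$gold
  gold_ann <- data.frame(doc_id = gold$doc_id, label = gold$label,
                         start = gold$start, end = gold$end,
                         text = gold$text, stringsAsFactors = FALSE)
  gold_ann$codes <- rep(list(character(0)), nrow(gold_ann))
  class(gold_ann) <- c("mention_set", "data.frame")
  write_annotations(gold_ann, file.path(dir, "ner_gold.tsv"),
                    with_codes = FALSE)
  for (m in seq_along(ner$member_predictions)) {
    p <- ner$member_predictions[[m]]
    ann <- data.frame(doc_id = p$doc_id, label = p$label, start = p$start,
                      end = p$end, text = "-", stringsAsFactors = FALSE)
    ann$codes <- rep(list(character(0)), nrow(ann))
    class(ann) <- c("mention_set", "data.frame")
    write_annotations(ann, file.path(dir, sprintf("ner_member%02d.tsv", m)),
                      with_codes = FALSE)
  }
  invisible(dir)
}
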