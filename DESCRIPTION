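Package: wntlink
Title: Gazetteer-Based Clinical Entity Linking with a Temperature-Scaled
    Cosine-Softmax Head
Version: 0.1.0
Authors@R: person("wntlink", "maintainers", email = "wntlink@example.org",
    role = c("aut", "cre"))
Description: Tools for normalizing clinical entity mentions against a flat
    concept gazetteer (SNOMED-CT style code/term/semantic-tag tables).
    Implements a dense-retrieval candidate generator over frozen term
    embeddings, a temperature-scaled cosine-softmax classification head whose
    per-concept weights are initialized as the mean embedding of all terms
    mapped to that concept, mini-batch fine-tuning of that head, IOB
    sequence-labeling utilities with exact-span majority voting for NER
    ensembles, strict-span and top-k evaluation, and a synthetic-data
    generator so the whole pipeline is testable without external corpora or
    pretrained encoders.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
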