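library(dplyr)

toy_obo_path <- function() {
  system.file("extdata", "toy.obo", package = "phenorag")
}

toy_json_path <- function() {
  system.file("extdata", "toy.json", package = "phenorag")
}

# Full small pipeline: ontology -> corpus -> split -> KB, returned together.
make_toy_pipeline <- function(n_terms = 3, seed = 7, n_per_term = 40,
                              kb_per_term = 32, test_per_term = 2,
                              drop_kb_terms = character()) {
  ontology <- simulate_ontology(n_terms, seed = seed)
  corpus <- generate_corpus(ontology, n_per_term = n_per_term, seed = seed) |>
    split_corpus(kb_per_term = kb_per_term, test_per_term = test_per_term)
  kb_rows <- filter(corpus, split == "kb", !term_id %in% drop_kb_terms) |>
    left_join(as_tibble(ontology)[, c("term_id", "label")], by = "term_id")
  kb <- build_kb(kb_rows)
  list(ontology = ontology, corpus = corpus, kb = kb,
       test = filter(corpus, split == "test"))
}

# Independent full-scan retrieval oracle: per-entry cosine via
# cosine_similarity(), sorted with base order(); no shared code with
# kb_query()'s matrix path.
brute_force_hits <- function(vectors, meta, query, k) {
  sims <- vapply(seq_len(nrow(vectors)),
                 function(i) cosine_similarity(vectors[i, ], query),
                 numeric(1))
  ord <- order(-sims, meta$insert_index)
  top <- ord[seq_len(min(k, length(ord)))]
  tibble::tibble(term_id = meta$term_id[top], similarity = sims[top],
                 rank = seq_along(top), kb_insert_index = meta$insert_index[top])
}

random_hp_ids <- function(n, pool = 50) {
  sprintf("HP:%07d", sample.int(pool, n, replace = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
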