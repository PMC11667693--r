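#' Build a vector knowledge base from annotated sentences
#'
#' Embeds each sentence and stores the vector alongside its source HPO
#' metadata (term id, label, sentence text). Queries are answered by an
#' exact full-scan cosine-similarity search; insertion order is preserved
#' as `insert_index` (0-based) and breaks similarity ties deterministically.
#'
#' @param entries Tibble with columns `term_id`, `label`, `text`. A
#'   precomputed vector matrix (rows aligned with `entries`) may be passed
#'   as `vectors`; otherwise texts are embedded with `backend`.
#' @param backend An [embedding_backend()] spec.
#' @param vectors Optional numeric matrix `nrow(entries)` x `backend$dim`.
#' @return A `hpo_kb` object.
#' @examples
#' ont <- simulate_ontology(3)
#' corpus <- split_corpus(generate_corpus(ont, n_per_term = 6, seed = 1),
#'                        kb_per_term = 4, test_per_term = 2)
#' kb <- build_kb(dplyr::filter(corpus, split == "kb") |>
#'                  dplyr::left_join(ont[, c("term_id", "label")], by = "term_id"))
#' @export
build_kb <- function(entries, backend = embedding_backend(), vectors = NULL) {
  stopifnot(inherits(backend, "phenorag_backend"))
  entries <- as_tibble(entries)
  if (nrow(entries) == 0) abort_validation("cannot build an empty knowledge base")
  needed <- c("term_id", "label", "text")
  if (!all(needed %in% names(entries))) {
    abort_validation(sprintf("entries need columns: %s", paste(needed, collapse = ", ")))
  }
  if (is.null(vectors)) {
    vectors <- embed_texts(entries$text, backend)
  } else {
    vectors <- as.matrix(vectors)
    if (nrow(vectors) != nrow(entries)) {
      abort_validation("vectors and entries disagree on entry count")
    }
    if (ncol(vectors) != backend$dim) {
      abort_validation(sprintf("vector dimension %d does not match backend dim %d",
                               ncol(vectors), backend$dim))
    }
    if (!all(is.finite(vectors))) abort_validation("vectors contain non-finite values")
  }
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms == 0)) abort_validation("zero-norm vector in knowledge base")
  meta <- tibble(insert_index = seq_len(nrow(entries)) - 1L,
                 term_id = entries$term_id,
                 label = entries$label,
                 sentence_text = entries$text)
  structure(list(vectors = vectors, norms = norms, meta = meta,
                 backend = backend[c("name", "dim", "normalization")]),
            class = "hpo_kb")
}

#' @export
print.hpo_kb <- function(x, ...) {
  cat(sprintf("<hpo_kb> %d entries, %d terms, backend %s (dim %d, %s)\n",
              nrow(x$meta), length(unique(x$meta$term_id)),
              x$backend$name, x$backend$dim, x$backend$normalization))
  invisible(x)
}

# Deterministic row-wise dot product: unlike BLAS gemv, the summation
# order is identical for every row, so duplicated entries give bitwise
# equal similarities and tie-breaking by insertion order is exact.
kb_dot <- function(vectors, query) {
  rowSums(vectors * rep(query, each = nrow(vectors)))
}

#' Number of entries in a knowledge base
#' @param kb A `hpo_kb`.
#' @return Integer entry count.
#' @export
kb_size <- function(kb) nrow(kb$meta)

#' Query a knowledge base
#'
#' Exact top-k cosine-similarity search over all stored vectors. Ties are
#' broken by ascending insertion index; entries from the same term are not
#' collapsed, so a top-5 list may repeat a term id.
#'
#' @param kb A `hpo_kb` from [build_kb()] or [load_kb()].
#' @param query Numeric vector of length `kb$backend$dim`, or a single
#'   string to embed with the KB's backend (hash-ngram only).
#' @param k Number of hits (>= 1); capped at the KB size.
#' @return Tibble with `term_id`, `similarity`, `rank`, `kb_insert_index`,
#'   sorted by decreasing similarity.
#' @export
kb_query <- function(kb, query, k = 1L) {
  stopifnot(inherits(kb, "hpo_kb"), k >= 1)
  if (is.character(query)) {
    backend <- do.call(embedding_backend, kb$backend)
    query <- drop(embed_texts(query, backend))
  }
  query <- as.numeric(query)
  if (length(query) != kb$backend$dim) {
    abort_validation(sprintf("query dimension %d does not match KB dim %d",
                             length(query), kb$backend$dim))
  }
  qn <- sqrt(sum(query^2))
  if (qn == 0) abort_validation("cannot query with a zero-norm vector")
  sims <- kb_dot(kb$vectors, query) / (kb$norms * qn)
  sims <- pmax(-1, pmin(1, sims))
  ord <- order(-sims, kb$meta$insert_index)
  top <- ord[seq_len(min(k, length(ord)))]
  tibble(term_id = kb$meta$term_id[top],
         similarity = sims[top],
         rank = seq_along(top),
         kb_insert_index = kb$meta$insert_index[top])
}

#' Persist / restore a knowledge base
#'
#' On-disk layout: `manifest.json` (backend name, dim, normalization, entry
#' count), `metadata.jsonl` (one entry per line, insertion order) and
#' `vectors.bin` (row-major little-endian IEEE-754 doubles), so a reloaded
#' KB answers every query bit-identically.
#'
#' @param kb A `hpo_kb`.
#' @param path Directory (created if needed).
#' @return `save_kb()` returns `path` invisibly; `load_kb()` the `hpo_kb`.
#' @export
save_kb <- function(kb, path) {
  stopifnot(inherits(kb, "hpo_kb"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(format = "phenorag-kb", version = 1L,
                   backend = kb$backend, count = nrow(kb$meta),
                   endian = "little")
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  meta_lines <- purrr::map_chr(seq_len(nrow(kb$meta)), function(i) {
    jsonlite::toJSON(as.list(kb$meta[i, ]), auto_unbox = TRUE)
  })
  writeLines(meta_lines, file.path(path, "metadata.jsonl"))
  con <- file(file.path(path, "vectors.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(t(kb$vectors)), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_kb
#' @export
load_kb <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort_format(sprintf("missing KB manifest: %s", manifest_path))
  }
  manifest <- tryCatch(jsonlite::fromJSON(manifest_path),
                       error = function(e) {
                         abort_format(sprintf("corrupt KB manifest %s: %s",
                                              manifest_path, conditionMessage(e)))
                       })
  if (!identical(manifest$format, "phenorag-kb")) {
    abort_format(sprintf("%s is not a phenorag KB manifest", manifest_path))
  }
  count <- manifest$count
  dim <- manifest$backend$dim
  meta_path <- file.path(path, "metadata.jsonl")
  vec_path <- file.path(path, "vectors.bin")
  if (!file.exists(meta_path)) abort_format(sprintf("missing %s", meta_path))
  if (!file.exists(vec_path)) abort_format(sprintf("missing %s", vec_path))
  if (file.info(vec_path)$size != 8 * count * dim) {
    abort_format(sprintf("%s: size disagrees with manifest (%d entries x dim %d)",
                         vec_path, count, dim))
  }
  con <- file(vec_path, "rb")
  on.exit(close(con))
  values <- readBin(con, "double", n = count * dim, size = 8L, endian = "little")
  vectors <- matrix(values, nrow = count, ncol = dim, byrow = TRUE)
  meta_lines <- readLines(meta_path, warn = FALSE)
  if (length(meta_lines) != count) {
    abort_format(sprintf("%s: %d lines but manifest says %d entries",
                         meta_path, length(meta_lines), count))
  }
  meta <- bind_rows(purrr::map(meta_lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(insert_index = as.integer(rec$insert_index), term_id = rec$term_id,
           label = rec$label, sentence_text = rec$sentence_text)
  }))
  entries <- tibble(term_id = meta$term_id, label = meta$label,
                    text = meta$sentence_text)
  embed_fun <- if (identical(manifest$backend$name, "external")) {
    function(texts) abort_config(
      "this KB was built with an external encoder; query it with vectors")
  }
  backend <- embedding_backend(name = manifest$backend$name,
                               dim = as.integer(dim),
                               normalization = manifest$backend$normalization,
                               embed_fun = embed_fun)
  build_kb(entries, backend, vectors = vectors)
}
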