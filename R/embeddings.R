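#' Describe an embedding backend
#'
#' The package's reference backend, `"hash-ngram"`, is a deterministic
#' hashed character 3-gram vectorizer: text is NFC-normalised and
#' lowercased, padded with `^`/`$`, its character 3-grams are hashed with
#' 64-bit FNV-1a modulo `dim`, and the bucket-count vector is
#' L2-normalised. Pretrained sentence encoders can be plugged in as
#' `"external"` backends by supplying `embed_fun`, a function mapping a
#' character vector to a numeric matrix with `dim` columns.
#'
#' @param name Backend name, `"hash-ngram"` or `"external"`.
#' @param dim Embedding dimension (>= 2). Default 256.
#' @param normalization `"l2"` (default) or `"none"`.
#' @param embed_fun For external backends, the encoding function.
#' @return A `phenorag_backend` spec.
#' @export
embedding_backend <- function(name = "hash-ngram", dim = 256L,
                              normalization = c("l2", "none"),
                              embed_fun = NULL) {
  normalization <- match.arg(normalization)
  if (!name %in% c("hash-ngram", "external")) {
    abort_config(sprintf("unknown embedding backend: %s", name))
  }
  if (dim < 2) abort_validation("embedding dim must be >= 2")
  if (name == "external" && !is.function(embed_fun)) {
    abort_config("an external backend needs an `embed_fun` function")
  }
  structure(list(name = name, dim = as.integer(dim),
                 normalization = normalization, embed_fun = embed_fun),
            class = "phenorag_backend")
}

#' Embed texts with a backend
#'
#' @param texts Character vector; every element must be non-empty after
#'   trimming.
#' @param backend An [embedding_backend()] spec.
#' @return A numeric matrix, one row per text, `backend$dim` columns. With
#'   `normalization = "l2"` every row has unit Euclidean norm.
#' @examples
#' v <- embed_texts(c("short stature", "tall stature"), embedding_backend())
#' tcrossprod(v)  # pairwise cosine similarities
#' @export
embed_texts <- function(texts, backend = embedding_backend()) {
  stopifnot(inherits(backend, "phenorag_backend"))
  if (length(texts) == 0) abort_validation("no texts to embed")
  blank <- which(is.na(texts) | !nzchar(stringr::str_trim(texts)))
  if (length(blank) > 0) {
    abort_validation(sprintf("empty text at index %d", blank[1]))
  }
  mat <- if (backend$name == "hash-ngram") {
    norm_text <- stringi::stri_trans_tolower(stringi::stri_trans_nfc(texts))
    cpp_hash_ngram_counts(norm_text, backend$dim)
  } else {
    m <- backend$embed_fun(texts)
    if (!is.matrix(m) || nrow(m) != length(texts) || ncol(m) != backend$dim) {
      abort_format(sprintf("external backend returned wrong shape (want %d x %d)",
                           length(texts), backend$dim))
    }
    m
  }
  if (!all(is.finite(mat))) abort_validation("backend produced non-finite values")
  if (backend$normalization == "l2") {
    norms <- sqrt(rowSums(mat^2))
    zero <- norms == 0
    if (any(zero)) {
      abort_validation(sprintf("text at index %d embeds to the zero vector",
                               which(zero)[1]))
    }
    mat <- mat / norms
  }
  dimnames(mat) <- NULL
  mat
}

#' Hashed character 3-gram vector for one text
#'
#' @param text A single non-empty string.
#' @param dim Embedding dimension (>= 2).
#' @return A unit-norm numeric vector of length `dim`.
#' @export
hash_ngram_vector <- function(text, dim = 256L) {
  stopifnot(length(text) == 1)
  drop(embed_texts(text, embedding_backend(dim = dim)))
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against rounding.
#'
#' @param u,v Numeric vectors of equal length and nonzero norm.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v)) {
    abort_validation(sprintf("dimension mismatch: %d vs %d", length(u), length(v)))
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort_validation("cosine undefined for zero-norm input")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}
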