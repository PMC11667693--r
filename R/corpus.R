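#' @keywords internal
.prompt_template <- paste0(
  "Generate %d unique sentences that describe the provided HPO label as they ",
  "would appear in a clinical narrative or interpretive report. Each sentence ",
  "should offer a different perspective or detail, similar to how various ",
  "clinicians might report observations or diagnoses in clinical notes. Avoid ",
  "using the exact phrase in every sentence to ensure diversity and reflect ",
  "the range of clinical expression. Sometimes, I will provide comments, ",
  "synonyms, and definitions that can help provide more context for your ",
  "thoughts. Return a bulleted list instead of numbered. Feel free to use ",
  "clinical shorthand that a physician might use in writing reports.\n",
  "HPO label: %s\n",
  "Definition: %s\n",
  "Comments: %s\n",
  "Synonyms: %s")

#' Build the sentence-generation prompt for one term
#'
#' Renders the fixed prompt template with the term's label, definition,
#' comments and synonyms substituted. Missing optional fields render as the
#' literal `None` so the prompt structure never varies; synonyms are joined
#' with `"; "`.
#'
#' @param term A one-row ontology tibble (or list) with `label`,
#'   `definition`, `comments`, `synonyms`.
#' @param n_sentences Number of sentences requested (default 40).
#' @return The rendered prompt, a length-1 character vector.
#' @examples
#' ont <- simulate_ontology(1)
#' cat(build_prompt(ont[1, ]))
#' @export
build_prompt <- function(term, n_sentences = 40L) {
  stopifnot(n_sentences >= 1)
  label <- stringr::str_trim(term$label %||% "")
  if (is.na(label) || !nzchar(label)) {
    abort_validation("cannot build a prompt for a term without a label")
  }
  or_none <- function(x) {
    if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) "None" else x
  }
  synonyms <- term$synonyms
  if (is.list(synonyms)) synonyms <- synonyms[[1]]
  syn_text <- if (length(synonyms) == 0) "None" else paste(synonyms, collapse = "; ")
  sprintf(.prompt_template, n_sentences, label,
          or_none(term$definition), or_none(term$comments), syn_text)
}

#' Parse a bulleted LLM completion into sentences
#'
#' Accepts `-`, `*` and `•` bullets (and, as a fallback, `1.`/`2)`
#' numbered lines), strips the markers and surrounding whitespace, and skips
#' blank lines.
#'
#' @param raw The verbatim completion text.
#' @return Character vector of sentences in order of appearance.
#' @export
parse_bulleted_response <- function(raw) {
  lines <- unlist(strsplit(raw %||% "", "\n", fixed = TRUE))
  lines <- stringr::str_trim(lines)
  lines <- lines[nzchar(lines)]
  stripped <- sub("^([-*•]|\\d+[.)])\\s*", "", lines)
  stripped <- stringr::str_trim(stripped)
  stripped <- stripped[nzchar(stripped)]
  if (length(stripped) == 0) {
    abort_format("no sentences recovered from completion", raw = raw)
  }
  stripped
}

# Short clinical framings; {phrase} is replaced by the term's label or a
# synonym. Kept deliberately terse so the phrase dominates each sentence's
# character-3-gram profile (the separability guarantee).
.sentence_templates <- c(
  "{phrase} noted.", "Pt w/ {phrase}.", "Hx of {phrase}.",
  "{phrase} on exam.", "Exam: {phrase}.", "C/w {phrase}.",
  "{phrase} seen today.", "A/P: {phrase}.", "Dx: {phrase}.",
  "{phrase} since birth.", "New {phrase}.", "{phrase} confirmed.",
  "{phrase} suspected.", "R/o {phrase}.", "{phrase}, stable.",
  "{phrase}, worse.", "{phrase} at f/u.", "Imaging: {phrase}.",
  "MRI: {phrase}.", "US: {phrase}.", "{phrase} per records.",
  "{phrase} documented.", "Known {phrase}.", "{phrase} bilat.",
  "Mild {phrase}.", "Severe {phrase}.", "Progressive {phrase}.",
  "Congenital {phrase}.", "{phrase} per mom.",
  "{phrase} evident.", "Impression: {phrase}.", "{phrase} persists.",
  "{phrase} recurred.", "Stable {phrase}.", "{phrase} from age 2.",
  "{phrase} - monitor.", "{phrase}, no rx.", "Consult: {phrase}.",
  "Referral: {phrase}.", "{phrase} on review.", "{phrase} intraop.",
  "{phrase} per note.", "F/u: {phrase}.", "{phrase} unchanged."
)

# Per-term RNG seed derived by hashing (seed, term_id), so one term's
# sentence stream does not depend on term iteration order.
term_stream_seed <- function(seed, term_id) {
  cpp_fnv1a_mod(paste0(seed, "|", term_id), 2^31 - 1)
}

builtin_sentences <- function(term, n, seed) {
  phrases <- c(term$label, term$synonyms[[1]])
  n_tpl <- length(.sentence_templates)
  withr::with_seed(term_stream_seed(seed, term$term_id), {
    tpl_order <- sample.int(n_tpl)
    phrase_draw <- phrases[sample.int(length(phrases), n, replace = TRUE)]
  })
  idx <- seq_len(n) - 1L
  tpl <- .sentence_templates[tpl_order[(idx %% n_tpl) + 1L]]
  cycle <- idx %/% n_tpl
  text <- stringr::str_replace(tpl, stringr::fixed("{phrase}"), phrase_draw)
  text <- ifelse(cycle > 0L, sprintf("%s [encounter %d]", text, cycle + 1L), text)
  dup <- duplicated(text)
  if (any(dup)) text[dup] <- sprintf("%s [note %d]", text[dup], idx[dup])
  text
}

#' Generate a synthetic clinical corpus
#'
#' For each term, produces `n_per_term` sentences that use the term's label
#' or one of its synonyms in a short clinical framing. Two sentence sources
#' are supported:
#'
#' * `backend = "builtin"`: a deterministic seeded generator. Every sentence
#'   contains its term's label or a synonym verbatim, sentences are unique
#'   within a term, and the output is fully determined by
#'   `(term_id, index, seed)` regardless of term order.
#' * `backend = <function>`: an external LLM client taking the rendered
#'   prompt ([build_prompt()]) and returning the raw completion text, which
#'   is parsed with [parse_bulleted_response()]. Such clients may return
#'   fewer than `n_per_term` sentences; the shortfall is recorded per term.
#'
#' @param terms Ontology tibble (e.g. from [filter_terms()]).
#' @param n_per_term Sentences requested per term (default 40).
#' @param seed Corpus-level integer seed for the built-in generator.
#' @param backend `"builtin"` or a function `function(prompt) -> text`.
#' @return A tibble with columns `term_id`, `index` (0-based), `text`,
#'   `split` (initially `"unused"`).
#' @examples
#' ont <- simulate_ontology(3)
#' corpus <- generate_corpus(ont, n_per_term = 5, seed = 7)
#' @export
generate_corpus <- function(terms, n_per_term = 40L, seed = 1L,
                            backend = "builtin") {
  stopifnot(n_per_term >= 1)
  terms <- as_tibble(terms)
  if (nrow(terms) == 0) abort_validation("no terms to generate sentences for")
  if (any(is.na(terms$label) | !nzchar(stringr::str_trim(terms$label)))) {
    abort_validation("every term needs a non-empty label")
  }
  rows <- purrr::map(seq_len(nrow(terms)), function(i) {
    term <- terms[i, ]
    if (is.function(backend)) {
      raw <- tryCatch(backend(build_prompt(term, n_per_term)),
                      error = function(e) {
                        abort(sprintf("sentence backend failed for %s: %s",
                                      term$term_id, conditionMessage(e)),
                              class = "phenorag_backend_error", parent = e)
                      })
      text <- parse_bulleted_response(raw)
      if (length(text) > n_per_term) text <- text[seq_len(n_per_term)]
    } else if (identical(backend, "builtin")) {
      text <- builtin_sentences(term, n_per_term, seed)
    } else {
      abort_config(sprintf("unknown corpus backend: %s", format(backend)))
    }
    tibble(term_id = term$term_id, index = seq_along(text) - 1L, text = text)
  })
  out <- bind_rows(rows)
  out$split <- "unused"
  out
}

#' Assign knowledge-base / test splits within each term
#'
#' Implements the first-32 / next-2 split: per term, ordered by generation
#' index, the first `kb_per_term` sentences are marked `kb`, the next
#' `test_per_term` are marked `test`, and the remainder `unused`. Terms that
#' produced fewer than `kb_per_term + test_per_term` sentences keep their
#' last `test_per_term` sentences as the test set and shrink the KB side;
#' terms with `test_per_term` or fewer sentences contribute everything to
#' the KB and are flagged untestable in the attached summary.
#'
#' @param sentences Corpus tibble from [generate_corpus()].
#' @param kb_per_term Sentences per term for the knowledge base (default 32).
#' @param test_per_term Held-out sentences per term (default 2).
#' @return The corpus with `split` filled in; the per-term summary is
#'   attached as attribute `"split_summary"` (a tibble with `term_id`,
#'   `n_sentences`, `n_kb`, `n_test`, `untestable`).
#' @export
split_corpus <- function(sentences, kb_per_term = 32L, test_per_term = 2L) {
  stopifnot(kb_per_term >= 1, test_per_term >= 1)
  sentences <- as_tibble(sentences)
  if (anyDuplicated(sentences[, c("term_id", "index")])) {
    abort_validation("duplicate (term_id, index) pairs in corpus")
  }
  out <- sentences |>
    group_by(.data$term_id) |>
    arrange(.data$index, .by_group = TRUE) |>
    mutate(split = {
      n_i <- n()
      s <- rep("unused", n_i)
      if (n_i >= kb_per_term + test_per_term) {
        s[seq_len(kb_per_term)] <- "kb"
        s[kb_per_term + seq_len(test_per_term)] <- "test"
      } else if (n_i > test_per_term) {
        s <- rep("kb", n_i)
        s[n_i - test_per_term + seq_len(test_per_term)] <- "test"
      } else {
        s <- rep("kb", n_i)
      }
      s
    }) |>
    ungroup()
  summary <- out |>
    group_by(.data$term_id) |>
    summarise(n_sentences = n(),
              n_kb = sum(.data$split == "kb"),
              n_test = sum(.data$split == "test"),
              .groups = "drop") |>
    mutate(untestable = .data$n_test == 0)
  attr(out, "split_summary") <- summary
  out
}

#' Write / read a corpus as JSON Lines
#'
#' One JSON object per sentence with keys `term_id`, `index`, `text`,
#' `split`.
#'
#' @param sentences Corpus tibble.
#' @param path File path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()`
#'   returns the corpus tibble.
#' @export
write_corpus <- function(sentences, path) {
  lines <- purrr::map_chr(seq_len(nrow(sentences)), function(i) {
    jsonlite::toJSON(list(term_id = sentences$term_id[i],
                          index = sentences$index[i],
                          text = sentences$text[i],
                          split = sentences$split[i]),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("corpus file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_format(sprintf("empty corpus file: %s", path))
  rows <- purrr::map(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    tibble(term_id = rec$term_id, index = as.integer(rec$index),
           text = rec$text, split = rec$split %||% "unused")
  })
  bind_rows(rows)
}
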