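#' Construct a ranked prediction set
#'
#' A prediction set is one model's ordered (best-first) multiset of HPO ids
#' for one input sentence, holding at most `k` labels. Duplicates are
#' allowed: a retrieval model's top-5 list may repeat the same term id when
#' several neighbouring sentences share it.
#'
#' @param labels Character vector of HP ids, best first, length `0..k`.
#' @param k Rank cutoff the set was produced under.
#' @param source One of `"em"`, `"pt"`, `"lexical"`, `"fused"`.
#' @param sentence_key Identifier of the scored input.
#' @return A `phenorag_prediction` object.
#' @export
prediction_set <- function(labels, k, source = "em", sentence_key = NA_character_) {
  stopifnot(k >= 1)
  labels <- as.character(labels)
  if (length(labels) > k) {
    abort_validation(sprintf("%d labels exceed k = %d", length(labels), k))
  }
  if (length(labels) > 0 && !all(is_hp_id(labels))) {
    abort_validation("prediction labels must be HP:nnnnnnn ids")
  }
  if (!source %in% c("em", "pt", "lexical", "fused")) {
    abort_validation(sprintf("unknown prediction source: %s", source))
  }
  structure(list(source = source, sentence_key = sentence_key,
                 k = as.integer(k), labels = labels),
            class = "phenorag_prediction")
}

as_prediction <- function(x, k, source = "em") {
  if (inherits(x, "phenorag_prediction")) x else prediction_set(x, k, source)
}

#' @export
print.phenorag_prediction <- function(x, ...) {
  cat(sprintf("<prediction %s k=%d> %s\n", x$source, x$k,
              if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Embedding-retrieval prediction (the EM path)
#'
#' Embeds the sentence, retrieves the top-k nearest knowledge-base
#' sentences by cosine similarity, and reads each hit's HPO id off its
#' metadata. Always returns exactly `min(k, kb_size(kb))` labels.
#'
#' @param sentence A single non-empty string.
#' @param kb A `hpo_kb`.
#' @param k Number of neighbours (paper settings: 1 and 5).
#' @param sentence_key Optional identifier carried into the result.
#' @return A [prediction_set()] with `source = "em"`.
#' @export
em_predict <- function(sentence, kb, k = 1L, sentence_key = NA_character_) {
  hits <- kb_query(kb, sentence, k)
  prediction_set(hits$term_id, k, source = "em", sentence_key = sentence_key)
}

#' Lexical fallback tagger
#'
#' A dictionary-only stand-in for an external hybrid tagger: every ontology
#' label and synonym is searched in the sentence as a case-insensitive
#' whole phrase; matches are ranked by matched-phrase character length
#' (longest first), then ascending term id, and truncated to `k`. Unlike
#' the retrieval path it may return no labels at all.
#'
#' @param sentence A single string.
#' @param ontology An [new_ontology()] tibble.
#' @param k Rank cutoff.
#' @param sentence_key Optional identifier.
#' @return A [prediction_set()] with `source = "lexical"`.
#' @export
lexical_predict <- function(sentence, ontology, k = 1L,
                            sentence_key = NA_character_) {
  stopifnot(length(sentence) == 1)
  lex <- lexicon_table(ontology)
  hit <- stringr::str_detect(
    sentence, stringr::regex(lex$pattern, ignore_case = TRUE))
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) {
    return(prediction_set(character(), k, source = "lexical",
                          sentence_key = sentence_key))
  }
  matches <- lex[hit, ] |>
    group_by(.data$term_id) |>
    summarise(len = max(.data$len), .groups = "drop") |>
    arrange(dplyr::desc(.data$len), .data$term_id)
  prediction_set(utils::head(matches$term_id, k), k,
                 source = "lexical", sentence_key = sentence_key)
}

lexicon_table <- function(ontology) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  lex <- tibble(term_id = rep(ontology$term_id,
                              1L + lengths(ontology$synonyms)),
                phrase = unlist(purrr::map2(ontology$label, ontology$synonyms,
                                            ~ c(.x, .y))))
  lex$len <- nchar(lex$phrase)
  lex$pattern <- paste0("\\b", escape_regex(lex$phrase), "\\b")
  lex
}

escape_regex <- function(x) gsub("([][{}()|.\\\\^$*+?])", "\\\\\\1", x)

#' Read / write PubTator pipe-delimited records
#'
#' The exchange dialect used by biomedical taggers: per document a title
#' line `docid|t|title`, an abstract line `docid|a|abstract`, and a blank
#' separator line.
#'
#' @param path File path.
#' @param records Tibble with `doc_id`, `title`, `abstract`.
#' @return `read_pubtator()` returns that tibble; `write_pubtator()`
#'   returns `path` invisibly.
#' @export
read_pubtator <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("PubTator file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  docs <- list()
  open_title <- NULL  # c(doc_id, title)
  flush_open <- function(i) {
    if (!is.null(open_title)) {
      abort_format(sprintf("%s:%d: title line for doc '%s' has no abstract line",
                           path, i, open_title[1]))
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(stringr::str_trim(line))) next
    m <- regmatches(line, regexec("^([^|]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(m) == 0) {
      abort_format(sprintf("%s:%d: malformed PubTator line '%s'", path, i, line))
    }
    doc_id <- m[2]; kind <- m[3]; text <- m[4]
    if (kind == "t") {
      flush_open(i)
      open_title <- c(doc_id, text)
    } else {
      if (is.null(open_title) || open_title[1] != doc_id) {
        abort_format(sprintf(
          "%s:%d: abstract line for doc '%s' without a preceding title line",
          path, i, doc_id))
      }
      docs[[length(docs) + 1L]] <- tibble(doc_id = doc_id,
                                          title = open_title[2],
                                          abstract = text)
      open_title <- NULL
    }
  }
  flush_open(length(lines))
  if (length(docs) == 0) abort_format(sprintf("no PubTator records in %s", path))
  bind_rows(docs)
}

#' @rdname read_pubtator
#' @export
write_pubtator <- function(records, path) {
  records <- as_tibble(records)
  stopifnot(all(c("doc_id", "title", "abstract") %in% names(records)))
  if (any(!nzchar(records$doc_id))) abort_validation("doc_id must be non-empty")
  blocks <- purrr::map(seq_len(nrow(records)), function(i) {
    c(sprintf("%s|t|%s", records$doc_id[i], records$title[i]),
      sprintf("%s|a|%s", records$doc_id[i], records$abstract[i]),
      "")
  })
  writeLines(unlist(blocks), path)
  invisible(path)
}

#' Adapter for an external PhenoTagger-style tagger
#'
#' Bridges an already-installed external tagger into the prediction-set
#' contract. The tagger may be given either as an R function
#' `function(records, k) -> tibble(doc_id, labels)` (with `labels` a list
#' column of ranked HP ids), or as a shell command template containing
#' `{input}` and `{output}` placeholders: the records are written to
#' `{input}` in PubTator format, the command is run, and `{output}` is read
#' back as tab-separated `doc_id<TAB>HP:...,HP:...` lines (one per
#' document; documents may be absent, meaning no prediction). Labels are
#' truncated to the tagger's top `k`.
#'
#' @param records Tibble with `doc_id`, `title`, `abstract`.
#' @param k Rank cutoff.
#' @param tagger Function or command template string.
#' @return A list of [prediction_set()] objects (`source = "pt"`), one per
#'   record, keyed by `doc_id`.
#' @export
external_tagger_adapter <- function(records, k, tagger) {
  records <- as_tibble(records)
  ranked <- if (is.function(tagger)) {
    out <- tagger(records, k)
    if (!is.data.frame(out) || !all(c("doc_id", "labels") %in% names(out))) {
      abort_format("tagger function must return a tibble with doc_id and labels")
    }
    out
  } else if (is.character(tagger) && length(tagger) == 1) {
    run_command_tagger(records, tagger)
  } else {
    abort_config("`tagger` must be a function or a command template string")
  }
  purrr::map(records$doc_id, function(id) {
    labels <- ranked$labels[match(id, ranked$doc_id)][[1]]
    if (is.null(labels) || length(labels) == 0 || all(is.na(labels))) {
      labels <- character()
    }
    prediction_set(utils::head(labels, k), k, source = "pt", sentence_key = id)
  })
}

run_command_tagger <- function(records, template) {
  exe <- strsplit(stringr::str_trim(template), "\\s+")[[1]][1]
  if (Sys.which(exe) == "" && !file.exists(exe)) {
    abort_config(sprintf("external tagger executable not found: %s", exe))
  }
  input <- tempfile(fileext = ".pubtator")
  output <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(input, output)))
  write_pubtator(records, input)
  cmd <- stringr::str_replace_all(
    template, c("\\{input\\}" = input, "\\{output\\}" = output))
  status <- system(cmd)
  if (status != 0) {
    abort_config(sprintf("external tagger exited with status %d", status))
  }
  if (!file.exists(output)) {
    abort_format(sprintf("external tagger produced no output file %s", output))
  }
  lines <- readLines(output, warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines))]
  rows <- purrr::map(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 1 || !nzchar(parts[1])) {
      abort_format(sprintf("unparsable tagger output line: '%s'", l), raw = l)
    }
    labels <- if (length(parts) >= 2 && nzchar(parts[2])) {
      strsplit(parts[2], ",", fixed = TRUE)[[1]]
    } else {
      character()
    }
    tibble(doc_id = parts[1], labels = list(stringr::str_trim(labels)))
  })
  bind_rows(rows)
}
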