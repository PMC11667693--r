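#' Score single-label predictions against gold terms
#'
#' Each record carries one gold HPO id and at most one predicted id.
#' Scoring: a correct prediction is one true positive; a wrong (non-empty)
#' prediction counts as both a false positive for the predicted id and a
#' false negative for the gold id; an empty prediction is a false negative
#' only. Consequently `tp + fn` always equals the number of records.
#'
#' @param records Tibble with `gold` and `predicted` (list column of
#'   character vectors, each of length 0 or 1).
#' @return Tibble with one row: `tp`, `fp`, `fn`.
#' @export
score_top1 <- function(records) {
  records <- as_tibble(records)
  lens <- lengths(records$predicted)
  if (any(lens > 1)) {
    abort_validation("records with more than one prediction: use score_topk()")
  }
  first <- purrr::map_chr(records$predicted,
                          ~ if (length(.x)) .x[1] else NA_character_)
  correct <- !is.na(first) & first == records$gold
  wrong <- !is.na(first) & first != records$gold
  empty <- is.na(first)
  tibble(tp = sum(correct), fp = sum(wrong), fn = sum(wrong) + sum(empty))
}

#' Score top-k prediction lists against gold terms
#'
#' A record is a true positive if its gold id appears anywhere in the
#' predicted multiset and a false negative otherwise. False positives
#' count predicted labels that differ from the gold id; under the default
#' `"multiset"` policy every occurrence counts (duplicates included, even
#' alongside a hit), under `"distinct"` each wrong id counts once per
#' record.
#'
#' @param records Tibble with `gold` and `predicted` (list column,
#'   lengths `0..k`).
#' @param k Rank cutoff the predictions were made under.
#' @param fp_policy `"multiset"` (default) or `"distinct"`.
#' @return Tibble with one row: `tp`, `fp`, `fn`.
#' @export
score_topk <- function(records, k, fp_policy = c("multiset", "distinct")) {
  fp_policy <- match.arg(fp_policy)
  records <- as_tibble(records)
  if (any(lengths(records$predicted) > k)) {
    abort_validation(sprintf("prediction list longer than k = %d", k))
  }
  hit <- purrr::map2_lgl(records$predicted, records$gold, ~ .y %in% .x)
  fp_per <- purrr::map2_int(records$predicted, records$gold, function(p, g) {
    wrong <- p[p != g]
    if (fp_policy == "distinct") length(unique(wrong)) else length(wrong)
  })
  tibble(tp = sum(hit), fp = sum(fp_per), fn = sum(!hit))
}

#' Sensitivity, PPV and F1 from confusion counts
#'
#' `sensitivity = tp / (tp + fn)`, `ppv = tp / (tp + fp)` (0 when nothing
#' was predicted), `f1 = 2 tp / (2 tp + fp + fn)` — the harmonic mean of
#' sensitivity and PPV.
#'
#' @param counts A list or one-row tibble with `tp`, `fp`, `fn`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `sensitivity`, `ppv`, `f1`.
#' @examples
#' compute_metrics(list(tp = 18253, fp = 13258, fn = 19139))
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  stopifnot(length(tp) == 1, length(fp) == 1, length(fn) == 1)
  if (any(c(tp, fp, fn) < 0)) abort_validation("negative confusion counts")
  if (tp + fn == 0) {
    abort_validation("no gold-bearing records: tp + fn = 0")
  }
  ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (tp == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tibble(tp = tp, fp = fp, fn = fn,
         sensitivity = tp / (tp + fn), ppv = ppv, f1 = f1)
}

#' Evaluate a prediction path on held-out sentences
#'
#' Runs the selected model over every test sentence and scores it against
#' the sentence's source term:
#'
#' * `mode = "em"`: embedding retrieval against `kb`;
#' * `mode = "pt"`: the supplied tagger only;
#' * `mode = "fused"`: both, combined with [fuse_k1()] / [fuse_topk()].
#'
#' Fused results (and any `k = 1` run) are scored with [score_top1()];
#' top-k component runs with [score_topk()].
#'
#' @param test_sentences Corpus tibble rows with `term_id`, `index`,
#'   `text` (typically `split == "test"` rows from [split_corpus()]).
#' @param kb A `hpo_kb` (required for `"em"` and `"fused"`).
#' @param tagger A function `function(text, k, sentence_key) ->`
#'   [prediction_set()] or bare label vector (required for `"pt"` and
#'   `"fused"`); e.g. a [lexical_predict()] closure or an
#'   [external_tagger_adapter()] wrapper.
#' @param mode `"em"`, `"pt"` or `"fused"`.
#' @param k Rank cutoff (paper settings 1 and 5).
#' @param fp_policy Passed to [score_topk()].
#' @return A `hpo_eval` object; see [glance.hpo_eval()] for the metric row
#'   and [tidy.hpo_eval()] for the per-sentence audit trail.
#' @export
evaluate_pipeline <- function(test_sentences, kb = NULL, tagger = NULL,
                              mode = c("em", "pt", "fused"), k = 1L,
                              fp_policy = c("multiset", "distinct")) {
  mode <- match.arg(mode)
  fp_policy <- match.arg(fp_policy)
  test_sentences <- as_tibble(test_sentences)
  if (nrow(test_sentences) == 0) abort_validation("no test sentences supplied")
  if (mode %in% c("em", "fused") && !inherits(kb, "hpo_kb")) {
    abort_config(sprintf("mode '%s' needs a knowledge base", mode))
  }
  if (mode %in% c("pt", "fused") && !is.function(tagger)) {
    abort_config(sprintf("mode '%s' needs a tagger function", mode))
  }
  keys <- paste(test_sentences$term_id, test_sentences$index, sep = ":")

  em_labels <- if (mode %in% c("em", "fused")) {
    backend <- do.call(embedding_backend, kb$backend)
    q <- embed_texts(test_sentences$text, backend)
    purrr::map(seq_len(nrow(q)), function(i) {
      kb_query(kb, q[i, ], k)$term_id
    })
  }
  pt_labels <- if (mode %in% c("pt", "fused")) {
    purrr::map(seq_len(nrow(test_sentences)), function(i) {
      p <- tagger(test_sentences$text[i], k, keys[i])
      as_prediction(p, k, "pt")$labels
    })
  }

  audit <- tibble(sentence_key = keys,
                  gold = test_sentences$term_id,
                  text = test_sentences$text)
  if (!is.null(em_labels)) audit$em <- em_labels
  if (!is.null(pt_labels)) audit$pt <- pt_labels

  if (mode == "fused") {
    fused <- fuse_predictions(
      tibble(sentence_key = keys, labels = pt_labels),
      tibble(sentence_key = keys, labels = em_labels), k = k)
    fused <- fused[match(keys, fused$sentence_key), ]
    audit$fused <- fused$fused_label
    audit$rule_applied <- fused$rule_applied
    predicted <- purrr::map(fused$fused_label,
                            ~ if (is.na(.x)) character() else .x)
  } else {
    predicted <- if (mode == "em") em_labels else pt_labels
  }
  audit$predicted <- predicted

  records <- tibble(sentence_key = keys, gold = audit$gold, predicted = predicted)
  counts <- if (mode == "fused" || k == 1L) {
    top1 <- mutate(records, predicted = purrr::map(predicted, utils::head, 1L))
    score_top1(top1)
  } else {
    score_topk(records, k, fp_policy)
  }
  audit$outcome <- purrr::map2_chr(predicted, audit$gold, function(p, g) {
    if (length(p) == 0) "no_prediction"
    else if (g %in% p) "correct"
    else "wrong"
  })
  structure(list(metrics = compute_metrics(counts), audit = audit,
                 mode = mode, k = as.integer(k), fp_policy = fp_policy,
                 n = nrow(records)),
            class = "hpo_eval")
}

#' @export
print.hpo_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<hpo_eval> mode=%s k=%d  n=%d\n  TP %d  FP %d  FN %d\n  sensitivity %.3f  ppv %.3f  f1 %.3f\n",
    x$mode, x$k, x$n, m$tp, m$fp, m$fn, m$sensitivity, m$ppv, m$f1))
  invisible(x)
}

#' One-row metric summary of an evaluation
#'
#' @param x A `hpo_eval` from [evaluate_pipeline()].
#' @param ... Unused.
#' @return Tibble with `mode`, `k`, `n`, `tp`, `fp`, `fn`, `sensitivity`,
#'   `ppv`, `f1`.
#' @export
glance.hpo_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(mode = x$mode, k = x$k, n = x$n), x$metrics)
}

#' Per-sentence audit trail of an evaluation
#'
#' @param x A `hpo_eval`.
#' @param ... Unused.
#' @return Tibble with one row per scored sentence: key, gold id, the
#'   per-model ranked predictions, the scored prediction and its outcome
#'   class.
#' @export
tidy.hpo_eval <- function(x, ...) {
  x$audit
}

#' Bar chart of an evaluation's metrics
#'
#' @param object A `hpo_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpo_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    glance(object)[, c("sensitivity", "ppv", "f1")],
    cols = dplyr::everything(), names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("sensitivity", "ppv", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(title = sprintf("%s model, top-%d (n = %d)",
                                  toupper(object$mode), object$k, object$n),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare several evaluations in one plot
#'
#' @param evals Named list of `hpo_eval` objects (names become the model
#'   labels).
#' @return A ggplot object with one bar group per model.
#' @export
plot_model_comparison <- function(evals) {
  stopifnot(length(evals) >= 1, !is.null(names(evals)))
  df <- purrr::imap(evals, function(e, nm) {
    out <- glance(e)[, c("sensitivity", "ppv", "f1")]
    out$model <- nm
    out
  }) |> bind_rows() |>
    tidyr::pivot_longer(cols = c("sensitivity", "ppv", "f1"),
                        names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("sensitivity", "ppv", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "model") +
    ggplot2::theme_minimal()
}

#' Serialize a metrics report
#'
#' @param eval_or_metrics A `hpo_eval` or a metrics tibble from
#'   [compute_metrics()].
#' @param json_path,tsv_path Optional output paths (skipped when `NULL`).
#' @return The metric row, invisibly.
#' @export
write_metrics <- function(eval_or_metrics, json_path = NULL, tsv_path = NULL) {
  row <- if (inherits(eval_or_metrics, "hpo_eval")) {
    glance(eval_or_metrics)
  } else {
    as_tibble(eval_or_metrics)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(row), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(row, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(row)
}
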