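#' Fuse two k = 1 prediction sets (tagger precedence)
#'
#' At k = 1 the fused model assigns the shared label when the external
#' tagger (PT) and the retrieval model (EM) agree; when they disagree, the
#' PT label wins. If only one model produced a label it is used; if
#' neither did, the result is no prediction.
#'
#' @param pt,em [prediction_set()]s (or bare label vectors) with `k = 1`.
#' @param sentence_key Optional identifier for the fused result.
#' @return A one-row tibble with `sentence_key`, `fused_label` (`NA` when
#'   no prediction), `rule_applied`, and `pooled_counts` (list column of
#'   named integer vote counts).
#' @export
fuse_k1 <- function(pt, em, sentence_key = NA_character_) {
  pt <- as_prediction(pt, 1L, "pt")
  em <- as_prediction(em, 1L, "em")
  if (pt$k != 1L || em$k != 1L) {
    abort_validation("fuse_k1 requires k = 1 prediction sets")
  }
  pooled <- pool_counts(pt$labels, em$labels)
  if (length(pt$labels) == 1 && length(em$labels) == 1) {
    if (pt$labels == em$labels) {
      fused <- pt$labels; rule <- "unanimous_k1"
    } else {
      fused <- pt$labels; rule <- "pt_precedence_k1"
    }
  } else if (length(pt$labels) == 1) {
    fused <- pt$labels; rule <- "single_model_k1"
  } else if (length(em$labels) == 1) {
    fused <- em$labels; rule <- "single_model_k1"
  } else {
    fused <- NA_character_; rule <- "no_prediction"
  }
  fusion_row(sentence_key, fused, rule, pooled)
}

#' Fuse two top-k prediction sets by majority vote
#'
#' Pools the two ranked lists as a multiset (duplicates each count one
#' vote) and assigns the label with the highest combined count. Ties are
#' broken by the best (lowest) rank in the PT list, then the best rank in
#' the EM list, then ascending term id — a generalisation of the k = 1
#' tagger-precedence rule.
#'
#' @param pt,em [prediction_set()]s (or bare label vectors) produced under
#'   the same `k`.
#' @param k Rank cutoff (>= 2; use [fuse_k1()] for k = 1).
#' @param sentence_key Optional identifier.
#' @return A one-row tibble as in [fuse_k1()].
#' @examples
#' fuse_topk(rep(c("HP:0000002", "HP:0000098"), c(2, 3)),
#'           rep(c("HP:0000002", "HP:0000098"), c(4, 1)), k = 5)
#' @export
fuse_topk <- function(pt, em, k, sentence_key = NA_character_) {
  stopifnot(k >= 2)
  pt <- as_prediction(pt, k, "pt")
  em <- as_prediction(em, k, "em")
  if (pt$k != k || em$k != k) {
    abort_validation(sprintf("both prediction sets must carry k = %d", k))
  }
  pooled <- pool_counts(pt$labels, em$labels)
  if (length(pooled) == 0) {
    return(fusion_row(sentence_key, NA_character_, "no_prediction", pooled))
  }
  top <- max(pooled)
  contenders <- names(pooled)[pooled == top]
  if (length(contenders) == 1) {
    return(fusion_row(sentence_key, contenders, "majority_k5", pooled))
  }
  best_rank <- function(labels, x) {
    r <- match(x, labels)
    ifelse(is.na(r), Inf, r)
  }
  ord <- order(best_rank(pt$labels, contenders),
               best_rank(em$labels, contenders),
               contenders)
  fusion_row(sentence_key, contenders[ord[1]], "tie_break_k5", pooled)
}

pool_counts <- function(pt_labels, em_labels) {
  all_labels <- c(pt_labels, em_labels)
  if (length(all_labels) == 0) {
    return(integer())
  }
  counts <- table(all_labels)
  stats::setNames(as.integer(counts), names(counts))
}

fusion_row <- function(sentence_key, fused_label, rule, pooled) {
  tibble(sentence_key = sentence_key,
         fused_label = fused_label,
         rule_applied = rule,
         pooled_counts = list(pooled))
}

#' Fuse aligned tables of PT and EM predictions
#'
#' Vectorised driver over per-sentence prediction tables: rows are matched
#' on `sentence_key` and fused with [fuse_k1()] (`k = 1`) or [fuse_topk()].
#'
#' @param pt_tbl,em_tbl Tibbles with `sentence_key` and a `labels` list
#'   column of ranked HP ids.
#' @param k Rank cutoff both models were run at.
#' @return Tibble of fusion rows, one per sentence key present in either
#'   table (a key absent from one table counts as an empty prediction).
#' @export
fuse_predictions <- function(pt_tbl, em_tbl, k = 1L) {
  keys <- union(pt_tbl$sentence_key, em_tbl$sentence_key)
  rows <- purrr::map(keys, function(key) {
    pt_labels <- pt_tbl$labels[match(key, pt_tbl$sentence_key)][[1]] %||% character()
    em_labels <- em_tbl$labels[match(key, em_tbl$sentence_key)][[1]] %||% character()
    pt <- prediction_set(pt_labels, k, "pt", key)
    em <- prediction_set(em_labels, k, "em", key)
    if (k == 1L) fuse_k1(pt, em, key) else fuse_topk(pt, em, k, key)
  })
  bind_rows(rows)
}

#' Write fusion results as TSV
#'
#' Columns: `sentence_key`, `fused_label`, `rule_applied`,
#' `pooled_counts` (a JSON object per cell).
#'
#' @param fused Tibble from [fuse_predictions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fusion_tsv <- function(fused, path) {
  out <- tibble(
    sentence_key = fused$sentence_key,
    fused_label = fused$fused_label,
    rule_applied = fused$rule_applied,
    pooled_counts = purrr::map_chr(fused$pooled_counts, function(x) {
      as.character(jsonlite::toJSON(as.list(x), auto_unbox = TRUE))
    })
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
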