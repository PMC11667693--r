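records_of <- function(gold, preds) {
  tibble::tibble(sentence_key = sprintf("s%d", seq_along(gold)),
                 gold = gold, predicted = preds)
}

test_that("top-1 scoring counts a wrong prediction as both FP and FN", {
  g <- rep("HP:0000001", 3)
  counts <- score_top1(records_of(g, list("HP:0000001", "HP:0000009", character())))
  expect_equal(as.list(counts), list(tp = 1L, fp = 1L, fn = 2L))
  perfect <- score_top1(records_of(rep("HP:0000002", 10),
                                   rep(list("HP:0000002"), 10)))
  expect_equal(as.list(perfect), list(tp = 10L, fp = 0L, fn = 0L))
  silent <- score_top1(records_of(rep("HP:0000002", 10),
                                  rep(list(character()), 10)))
  expect_equal(as.list(silent), list(tp = 0L, fp = 0L, fn = 10L))
  expect_error(score_top1(records_of("HP:0000001", list(c("HP:0000001", "HP:0000002")))),
               class = "phenorag_validation_error")
})

test_that("top-1 scoring conserves tp + fn = n over random prediction tables", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    gold <- random_hp_ids(n)
    preds <- purrr::map(seq_len(n), function(j) {
      switch(sample(3, 1), random_hp_ids(1), gold[j], character())
    })
    counts <- score_top1(records_of(gold, preds))
    expect_equal(counts$tp + counts$fn, n)
    expect_true(counts$fp <= counts$fn)
  }
})

test_that("top-k scoring counts non-gold occurrences by multiset (or distinct)", {
  a <- "HP:0000001"; b <- "HP:0000002"; c <- "HP:0000003"
  r <- records_of(a, list(c(a, b, b, c, a)))
  counts <- score_topk(r, k = 5)
  expect_equal(as.list(counts), list(tp = 1L, fp = 3L, fn = 0L))
  distinct <- score_topk(r, k = 5, fp_policy = "distinct")
  expect_equal(as.list(distinct), list(tp = 1L, fp = 2L, fn = 0L))

  abstain <- score_topk(records_of(a, list(character())), k = 5)
  expect_equal(as.list(abstain), list(tp = 0L, fp = 0L, fn = 1L))

  two <- records_of(c(a, b), list(c(a, b, c, c, c), c(b, a, c, c, a)))
  expect_equal(as.list(score_topk(two, k = 5)),
               list(tp = 2L, fp = 8L, fn = 0L))
  expect_error(score_topk(records_of(a, list(rep(a, 6))), k = 5),
               class = "phenorag_validation_error")
})

test_that("metric arithmetic follows the harmonic-mean definitions with safe zeros", {
  perfect <- compute_metrics(list(tp = 10, fp = 0, fn = 0))
  expect_equal(perfect[c("sensitivity", "ppv", "f1")],
               tibble::tibble(sensitivity = 1, ppv = 1, f1 = 1))
  silent <- compute_metrics(list(tp = 0, fp = 0, fn = 5))
  expect_equal(as.numeric(silent[c("sensitivity", "ppv", "f1")]), c(0, 0, 0))
  expect_error(compute_metrics(list(tp = 0, fp = 3, fn = 0)),
               class = "phenorag_validation_error")
  set.seed(3)
  for (i in 1:30) {
    m <- compute_metrics(list(tp = sample(0:50, 1) + 1, fp = sample(0:50, 1),
                              fn = sample(0:50, 1)))
    expect_true(all(unlist(m[c("sensitivity", "ppv", "f1")]) >= 0 &
                      unlist(m[c("sensitivity", "ppv", "f1")]) <= 1))
    expect_true(m$f1 >= min(m$sensitivity, m$ppv) - 1e-12)
    expect_true(m$f1 <= max(m$sensitivity, m$ppv) + 1e-12)
    expect_equal(m$f1, 2 * m$tp / (2 * m$tp + m$fp + m$fn))
  }
})

test_that("the retrieval path scores perfectly on a separable toy corpus", {
  pipe <- make_toy_pipeline(n_terms = 3, seed = 7, n_per_term = 34)
  ev <- evaluate_pipeline(pipe$test, kb = pipe$kb, mode = "em", k = 1)
  expect_equal(glance(ev)$f1, 1)
  expect_equal(ev$n, 6)
  aud <- tidy(ev)
  expect_equal(nrow(aud), 6)
  expect_true(all(aud$outcome == "correct"))
})

test_that("fusing with an always-right tagger yields perfect sensitivity", {
  pipe <- make_toy_pipeline(n_terms = 3, seed = 11)
  oracle_tagger <- function(text, k, key) sub("^(HP:\\d{7}).*$", "\\1", key)
  ev <- evaluate_pipeline(pipe$test, kb = pipe$kb, tagger = oracle_tagger,
                          mode = "fused", k = 1)
  expect_equal(glance(ev)$sensitivity, 1)
  expect_true(all(tidy(ev)$rule_applied %in%
                    c("unanimous_k1", "pt_precedence_k1", "single_model_k1")))
})

test_that("retrieval against an unrelated knowledge base scores zero", {
  pipe <- make_toy_pipeline(n_terms = 3, seed = 13)
  other <- simulate_ontology(3, seed = 14)
  # give the foreign KB disjoint ids so no gold can ever be retrieved
  foreign <- generate_corpus(other, n_per_term = 10, seed = 1) |>
    mutate(term_id = sub("^HP:000000", "HP:000100", term_id)) |>
    left_join(tibble::tibble(term_id = sub("^HP:000000", "HP:000100", other$term_id),
                             label = other$label), by = "term_id")
  kb <- build_kb(rename(foreign, text = text))
  ev <- evaluate_pipeline(pipe$test, kb = kb, mode = "em", k = 1)
  expect_equal(glance(ev)$f1, 0)
})

test_that("evaluation objects expose tidy, glance and autoplot", {
  pipe <- make_toy_pipeline(n_terms = 3, seed = 21)
  ev <- evaluate_pipeline(pipe$test, kb = pipe$kb, mode = "em", k = 5)
  g <- glance(ev)
  expect_named(g, c("mode", "k", "n", "tp", "fp", "fn",
                    "sensitivity", "ppv", "f1"))
  # top-5 over a 3-term KB: every list has 5 labels, so fp grows fast
  expect_equal(g$tp + g$fn, g$n)
  expect_s3_class(autoplot(ev), "ggplot")
  expect_s3_class(plot_model_comparison(list(em = ev)), "ggplot")
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics(ev, json_path = path)
  expect_equal(jsonlite::fromJSON(path)$f1, g$f1)
})
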