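---
title: "Retrieval-augmented HPO term assignment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieval-augmented HPO term assignment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorag)
library(dplyr)
```

## The problem and the method

Clinical genetics workflows depend on structured phenotypes: free-text
notes have to be mapped onto Human Phenotype Ontology (HPO) concepts
before gene–phenotype prioritisation can use them. phenorag implements a
retrieval-based assignment strategy. Instead of training a classifier over
18,000+ labels, it builds a *knowledge base* of example sentences — for
every ontology term, short synthetic clinical sentences that use the
term's label, definition, comments and synonyms — embeds each sentence as
a dense vector, and stores the source term id as metadata next to the
vector. A new sentence is then embedded the same way and its top-k nearest
stored sentences under cosine similarity vote for its HPO id. We call this
retrieval path the embedding model (EM).

The package also wraps an external dictionary/ML tagger (a
PhenoTagger-style tool) behind an adapter contract, and combines the two
with late decision fusion: pool the two ranked top-k lists as a multiset
and take the label with the highest combined count. At k = 1 the rule
degenerates to: take the shared answer when the models agree, and prefer
the external tagger's answer when they disagree. The fused model (FM) is
the configuration that performed best in the study this design follows.

## Pipeline stages and their parameters

1. **Ontology ingestion** (`read_ontology()`): OBO 1.4 flat files or the
   official `hp.json` OBO-JSON layout. All synonym scopes (EXACT, BROAD,
   NARROW, RELATED) are accepted as synonyms, because the downstream
   prompt consumes "synonyms" without qualification. Obsolete terms are
   parsed and retained but excluded from corpus generation and KB
   building by default — the published term count does not state how it
   treated obsoletes, so the count is input-dependent here.
2. **Corpus generation** (`generate_corpus()`): 40 sentences are requested
   per term (`n_per_term = 40`). The prompt template (`build_prompt()`)
   renders the term's label, definition, comments and synonyms; missing
   optional fields render as the literal `None` so that the prompt
   structure never varies between terms. An external LLM client can be
   plugged in as a function from prompt to completion text; its bulleted
   output is parsed with `parse_bulleted_response()`. The test suite and
   the acceptance script use only the built-in deterministic generator
   (below).
3. **Split** (`split_corpus()`): the first 32 sentences per term go to the
   knowledge base, the next 2 are held out for testing, the remainder are
   unused (`kb_per_term = 32`, `test_per_term = 2`; 34 consumed per term).
   Generators often under-deliver, so a shortfall rule is needed: with
   between 3 and 33 sentences the *last two* stay in the test set and the
   KB side shrinks; with 2 or fewer everything goes to the KB and the term
   is flagged untestable in the split summary. Protecting the test side
   was chosen over dropping the term so that held-out coverage degrades
   gracefully; each affected term is visible in the summary log.
4. **Embedding** (`embed_texts()`): the reference backend is a hashed
   character 3-gram vectorizer — NFC-normalise, lowercase, pad with
   `^`/`$`, hash every character 3-gram with 64-bit FNV-1a modulo `dim`,
   and L2-normalise the bucket counts. Default `dim = 256`: large enough
   that toy corpora rarely collide in a bucket, small enough to keep test
   runs fast. Pretrained sentence encoders (the study compared
   instructor-large, MPNet-base-v2 and multiQA-MiniLM) plug in through the
   same `embedding_backend()` contract as `"external"` backends; nothing
   in the package downloads model weights.
5. **Retrieval** (`build_kb()`, `kb_query()`, `em_predict()`): the store is
   an exact in-memory full scan; results are sorted by cosine similarity,
   ties broken by ascending insertion index. Duplicate term ids in a
   top-5 list are kept — votes, not candidates. Approximate
   vector-database adapters can replace the scan but must reproduce the
   full-scan results at small scale; the method's results do not depend on
   ANN behaviour.
6. **Fusion** (`fuse_k1()`, `fuse_topk()`): majority vote over the pooled
   multiset. Two situations the vote leaves open are resolved
   deterministically: top-k ties break by the best rank in the external
   tagger's list, then the best rank in the retrieval list, then ascending
   term id (a generalisation of the k = 1 precedence rule); and when at
   k = 1 only one model produced a label, that label is used
   (`single_model_k1`), with "no prediction" reserved for the case where
   both models abstain — this keeps false-negative accounting meaningful
   rather than discarding answerable sentences.
7. **Evaluation** (`score_top1()`, `score_topk()`, `compute_metrics()`):
   one gold term per sentence. Under top-1 scoring a wrong prediction
   counts as *both* a false positive and a false negative, and an
   abstention as a false negative only, so `tp + fn` equals the number of
   scored sentences — the only rule consistent with the published
   confusion counts this scheme follows. Under top-k scoring, false
   positives count non-gold label occurrences as a multiset by default;
   `fp_policy = "distinct"` counts each wrong id once per sentence, since
   the published top-5 counts cannot discriminate between the two
   variants.

## The deterministic generator and what it does (not) emulate

The built-in generator exists so that every downstream property —
retrieval exactness, split accounting, fusion rules, metric arithmetic —
is testable offline with no LLM and no pretrained weights. Each sentence
is a short clinical framing ("Dx: {phrase}.", "{phrase} at f/u.",
44 distinct templates) around the term's label or one of its synonyms,
chosen by an RNG stream seeded from a hash of `(seed, term_id)` so a
term's sentences do not depend on term iteration order. Template order is
a seeded permutation; when more sentences are requested than templates
exist, an encounter stamp keeps texts unique within the term.

Two calibration choices make the toy conditions *separable*: templates
carry at most ~13 non-phrase characters, and the bundled synthetic
ontology (`simulate_ontology()`) assigns every term its own adjective and
its own anatomical structure, never reusing a content word across terms.
Under those conditions the phrase dominates each sentence's 3-gram
profile and top-1 retrieval recovers every held-out sentence's term — the
property the retrieval-recovery tests assert exactly (F1 = 1.0).

That is also what passing these tests does *not* show: real clinical
language shares vocabulary heavily across phenotypes, paraphrases instead
of quoting labels, and mixes several findings per sentence, and real
corpora are embedded with trained encoders whose geometry differs from
hashed n-grams. The synthetic results validate the machinery (exact
retrieval, split bookkeeping, fusion and scoring arithmetic), not
clinical-grade accuracy; published corpus-level scores (F1 ≈ 0.64 for
retrieval alone, ≈ 0.70 fused, over 37,392 held-out sentences) depend on
an undistributed LLM-generated corpus and specific pretrained weights and
are out of scope here.

## Numerical choices

- **Similarity kernel**: stored vectors and queries are compared with a
  row-deterministic dot product (identical entries give bitwise-identical
  similarities) rather than BLAS `gemv`, whose blocked summation can
  differ in the last bit by row position; this makes tie-breaking by
  insertion order exact and reproducible.
- **Ties**: ascending insertion index everywhere in retrieval; the
  three-stage rule above in fusion. Both are total orders, so runs are
  byte-reproducible.
- **Cosine** values are clamped to [-1, 1] against rounding; zero-norm
  inputs are rejected rather than silently mapped.
- **Persistence**: the KB directory stores a JSON manifest, JSON-Lines
  metadata in insertion order, and the raw row-major little-endian
  IEEE-754 double matrix, so `load_kb()` answers every query identically
  to the saved store.
- **Metrics edge cases**: PPV is defined as 0 when nothing was predicted;
  F1 as 0 when `tp = 0` with errors present; evaluation refuses inputs
  with no gold-bearing records.
- **Degenerate inputs**: empty texts are rejected before embedding (they
  would hash to the zero vector); one-character texts embed via their
  padded boundary grams.

## Problem sizes used by the checks

The test suite exercises ontologies of 3–60 terms with 34–50 sentences per
term, random stores of up to 1,000 vectors at dimension 256 against a
brute-force oracle, and a full-size split-accounting check (18,696 terms x
34 sentences, confirming 2 x 18,696 = 37,392 held-out sentences). The
acceptance script runs the complete pipeline — 50-term ontology, 40
sentences per term, 1,600-entry KB, 100 held-out sentences — for the
retrieval, tagger and fused paths at k = 1 and reports their
sensitivity/PPV/F1. These sizes were chosen as the smallest conditions
that still exhibit every behaviour the method defines (shortfall splits,
ties, fusion disagreements).

## Known limitations

- The built-in lexical tagger is a dictionary matcher, not a
  re-implementation of PhenoTagger; it exists so fusion and evaluation are
  fully testable offline. Real taggers attach via
  `external_tagger_adapter()`.
- One gold term per sentence: multi-phenotype sentences, negation and
  family history are out of scope, as in the design this follows.
- No ontology-aware partial credit (an ancestor of the gold term scores as
  wrong).
- The external-LLM client contract is synchronous and unbatched; driving a
  commercial API at corpus scale is out of scope.
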