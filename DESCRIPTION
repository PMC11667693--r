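Package: phenorag
Title: Retrieval-Augmented Recognition of Human Phenotype Ontology Terms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns Human Phenotype Ontology (HPO) terms to free-text
    clinical sentences by embedding-based retrieval. Synthetic clinical
    sentences are generated for every ontology term, embedded, and stored
    in a vector knowledge base with the source term as metadata; a query
    sentence is embedded and the HPO ids of its top-k cosine-similarity
    neighbours become its predictions. Retrieval predictions can be fused
    with an external tagger's ranked output by majority vote with
    tagger precedence at k = 1. Includes OBO and OBO-JSON ontology
    readers, a PubTator reader/writer, a deterministic hashed character
    n-gram embedding backend, a lexical fallback tagger, and
    sensitivity/PPV/F1 evaluation with per-sentence audit trails.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stringi,
    stringr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
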