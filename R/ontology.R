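#' Construct an HPO ontology table
#'
#' An ontology is a tibble with one row per term and columns `term_id`,
#' `label`, `definition`, `comments`, `synonyms` (list column of character
#' vectors) and `is_obsolete`. Term ids must match `HP:` followed by seven
#' digits, labels must be non-empty, and a term's synonym list never
#' duplicates itself or the label.
#'
#' @param terms A data frame with at least `term_id` and `label` columns.
#'   Missing optional columns are filled (`definition`/`comments` with `NA`,
#'   `synonyms` with empty vectors, `is_obsolete` with `FALSE`).
#' @param source_path Path the ontology was read from, if any.
#' @param source_format One of `"obo"`, `"obo_json"`, `"synthetic"`.
#' @return A tibble of class `hpo_ontology`.
#' @export
new_ontology <- function(terms, source_path = NA_character_,
                         source_format = "synthetic") {
  terms <- as_tibble(terms)
  if (nrow(terms) == 0) {
    abort_format("an ontology must contain at least one term")
  }
  if (!all(c("term_id", "label") %in% names(terms))) {
    abort_validation("ontology terms need `term_id` and `label` columns")
  }
  if (!"definition" %in% names(terms)) terms$definition <- NA_character_
  if (!"comments" %in% names(terms)) terms$comments <- NA_character_
  if (!"synonyms" %in% names(terms)) {
    terms$synonyms <- rep(list(character()), nrow(terms))
  }
  if (!"is_obsolete" %in% names(terms)) terms$is_obsolete <- FALSE

  bad_id <- terms$term_id[!is_hp_id(terms$term_id)]
  if (length(bad_id) > 0) {
    abort_validation(sprintf("invalid HPO id(s): %s",
                             paste(utils::head(bad_id, 3), collapse = ", ")))
  }
  if (anyDuplicated(terms$term_id)) {
    abort_validation("duplicate term_id in ontology")
  }
  terms$label <- stringr::str_trim(terms$label)
  if (any(is.na(terms$label) | terms$label == "")) {
    abort_validation("every term needs a non-empty label")
  }
  terms$synonyms <- purrr::map2(terms$synonyms, terms$label, function(syn, lab) {
    syn <- stringr::str_trim(as.character(syn))
    unique(syn[!is.na(syn) & syn != "" & syn != lab])
  })
  out <- terms[, c("term_id", "label", "definition", "comments",
                   "synonyms", "is_obsolete")]
  structure(out,
            source_path = source_path,
            source_format = source_format,
            class = c("hpo_ontology", class(out)))
}

#' Read an HPO ontology file
#'
#' Parses either an OBO 1.4 flat file or the official `hp.json` OBO-JSON
#' layout (`graphs[[1]]$nodes`) into an ontology table. Every stanza/node
#' whose id matches `HP:nnnnnnn` is kept, including obsolete terms; IRI-form
#' ids (`.../HP_0000118`) are converted to `HP:0000118`. Synonym scope
#' qualifiers and surrounding quotes are stripped; multiple `def`/`comment`
#' lines are concatenated with a single space.
#'
#' @param path Path to the ontology file.
#' @param format `"obo"`, `"obo_json"`, or `"auto"` (detect by extension,
#'   then by content sniffing).
#' @return An [new_ontology()] tibble.
#' @examples
#' obo <- system.file("extdata", "toy.obo", package = "phenorag")
#' read_ontology(obo)
#' @export
read_ontology <- function(path, format = c("auto", "obo", "obo_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_io(sprintf("ontology file not found: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("obo")) {
      format <- "obo"
    } else if (ext %in% c("json")) {
      format <- "obo_json"
    } else {
      first <- readLines(path, n = 1L, warn = FALSE)
      format <- if (length(first) > 0 && grepl("^\\s*\\{", first)) "obo_json" else "obo"
    }
  }
  terms <- switch(format,
    obo = parse_obo_terms(path),
    obo_json = parse_obo_json_terms(path)
  )
  if (nrow(terms) == 0) {
    abort_format(sprintf("no HP terms parsed from %s (format %s)", path, format))
  }
  new_ontology(terms, source_path = path, source_format = format)
}

strip_obo_quoted <- function(value, line_no, path) {
  m <- regmatches(value, regexpr('"(\\\\.|[^"\\\\])*"', value))
  if (length(m) == 0) {
    abort_format(sprintf("%s:%d: expected a quoted value in '%s'",
                         path, line_no, value))
  }
  inner <- substr(m, 2, nchar(m) - 1)
  gsub('\\\\(["\\\\])', "\\1", inner)
}

parse_obo_terms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  boundaries <- c(grep("^\\[.+\\]$", lines), length(lines) + 1L)
  records <- list()
  for (s in stanza_starts) {
    end <- min(boundaries[boundaries > s]) - 1L
    rec <- list(id = NA_character_, name = NA_character_,
                def = character(), comment = character(),
                synonyms = character(), is_obsolete = FALSE)
    for (i in seq(s + 1L, length.out = max(0L, end - s))) {
      line <- lines[i]
      if (grepl("^\\s*$", line) || grepl("^!", line)) next
      line <- sub("\\s+!.*$", "", line)  # trailing OBO comments
      if (!grepl("^[A-Za-z_]+:", line)) {
        abort_format(sprintf("%s:%d: malformed tag line '%s'", path, i, line))
      }
      tag <- sub(":.*$", "", line)
      value <- stringr::str_trim(sub("^[A-Za-z_]+:\\s*", "", line))
      if (tag == "id") rec$id <- value
      else if (tag == "name") rec$name <- value
      else if (tag == "def") rec$def <- c(rec$def, strip_obo_quoted(value, i, path))
      else if (tag == "comment") rec$comment <- c(rec$comment, value)
      else if (tag == "synonym") {
        rec$synonyms <- c(rec$synonyms, strip_obo_quoted(value, i, path))
      } else if (tag == "is_obsolete") rec$is_obsolete <- identical(value, "true")
    }
    if (is.na(rec$id) || !grepl("^HP:", rec$id)) next
    if (is.na(rec$name)) {
      abort_format(sprintf("%s: term stanza at line %d (%s) has no name",
                           path, s, rec$id))
    }
    records[[length(records) + 1L]] <- tibble(
      term_id = rec$id,
      label = rec$name,
      definition = if (length(rec$def)) paste(rec$def, collapse = " ") else NA_character_,
      comments = if (length(rec$comment)) paste(rec$comment, collapse = " ") else NA_character_,
      synonyms = list(rec$synonyms),
      is_obsolete = rec$is_obsolete
    )
  }
  bind_rows(records)
}

iri_to_hp <- function(id) {
  id <- sub("^.*[/#]", "", id)
  sub("^HP_(\\d{7})$", "HP:\\1", id)
}

parse_obo_json_terms <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort_format(sprintf("cannot parse %s as OBO-JSON: %s",
                                         path, conditionMessage(e)))
                  })
  nodes <- tryCatch(doc$graphs[[1]]$nodes, error = function(e) NULL)
  if (is.null(nodes)) {
    abort_format(sprintf("%s: no graphs[[1]]$nodes found", path))
  }
  records <- purrr::map(nodes, function(node) {
    id <- iri_to_hp(node$id %||% "")
    if (!is_hp_id(id)) return(NULL)
    meta <- node$meta %||% list()
    syns <- purrr::map_chr(meta$synonyms %||% list(), ~ .x$val %||% NA_character_)
    comments <- unlist(meta$comments %||% list(), use.names = FALSE)
    tibble(
      term_id = id,
      label = node$lbl %||% NA_character_,
      definition = meta$definition$val %||% NA_character_,
      comments = if (length(comments)) paste(comments, collapse = " ") else NA_character_,
      synonyms = list(syns[!is.na(syns)]),
      is_obsolete = isTRUE(meta$deprecated)
    )
  })
  bind_rows(purrr::compact(records))
}

#' Select ontology terms in deterministic order
#'
#' @param ontology An [new_ontology()] tibble.
#' @param include_obsolete Keep obsolete terms? Default `FALSE`.
#' @return A tibble of terms sorted by ascending `term_id`.
#' @export
filter_terms <- function(ontology, include_obsolete = FALSE) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  out <- as_tibble(ontology)
  if (!include_obsolete) out <- filter(out, !.data$is_obsolete)
  arrange(out, .data$term_id)
}

#' Write an ontology as a toy OBO file
#'
#' Emits the subset of OBO 1.4 used by the reader (`id`, `name`, `def`,
#' `comment`, `synonym`, `is_obsolete` tags), so that
#' `read_ontology(write_obo(x, f))` round-trips ids, labels and synonyms.
#'
#' @param ontology An [new_ontology()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  esc <- function(x) gsub('(["\\\\])', "\\\\\\1", x)
  out <- c("format-version: 1.4", "")
  for (i in seq_len(nrow(ontology))) {
    row <- ontology[i, ]
    stanza <- c("[Term]",
                paste0("id: ", row$term_id),
                paste0("name: ", row$label))
    if (!is.na(row$definition)) {
      stanza <- c(stanza, sprintf('def: "%s" []', esc(row$definition)))
    }
    if (!is.na(row$comments)) {
      stanza <- c(stanza, paste0("comment: ", row$comments))
    }
    for (s in row$synonyms[[1]]) {
      stanza <- c(stanza, sprintf('synonym: "%s" EXACT []', esc(s)))
    }
    if (row$is_obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Vocabulary for the synthetic ontology factory. Each term draws one
# adjective and one anatomical structure, neither reused by another term,
# so terms share no content words: a sentence's phrase stays the dominant
# 3-gram signal linking it to its source term (the separability guarantee).
.pheno_adjectives <- c(
  "hypoplastic", "rudimentary", "misshapen", "atrophic", "bulky",
  "calcified", "fibrotic", "edematous", "sclerotic", "cystic",
  "nodular", "ulcerated", "stenotic", "dilated", "elongated",
  "foreshortened", "thickened", "attenuated", "fused", "bifid",
  "duplicated", "displaced", "rotated", "angulated", "bowed",
  "fragmented", "eroded", "pitted", "ridged", "furrowed",
  "mottled", "pigmented", "pallid", "translucent", "opacified",
  "vascularized", "bloodless", "necrotic", "gangrenous", "prolapsed",
  "herniated", "everted", "transposed", "retracted", "protuberant",
  "deviated", "asymmetric", "overgrown", "ossified", "demineralized",
  "granular", "striated", "scalloped", "serrated", "lobulated",
  "pedunculated", "indurated", "macerated", "friable", "telangiectatic"
)
.pheno_structures <- c(
  "femoral neck", "radial shaft", "ulnar styloid", "carpal bones",
  "distal phalanx", "tibial plateau", "fibular head", "tarsal arch",
  "calcaneal tendon", "patellar facet", "nasal septum", "frontal sinus",
  "ethmoid roof", "orbital floor", "zygomatic prominence", "mandibular ramus",
  "maxillary ridge", "dental enamel", "lingual frenulum", "palatine raphe",
  "thyroid isthmus", "cricoid ring", "tracheal lumen", "bronchial tree",
  "pulmonary hilum", "pleural lining", "cardiac apex", "mitral leaflet",
  "aortic root", "venous plexus", "hepatic lobule", "biliary duct",
  "pancreatic tail", "splenic capsule", "gastric fundus", "duodenal bulb",
  "jejunal loops", "ileal mucosa", "colonic haustra", "rectal vault",
  "renal pelvis", "ureteral orifice", "vesical trigone", "urethral meatus",
  "adrenal cortex", "ovarian follicle", "uterine cervix", "perineal body",
  "inguinal ligament", "umbilical stump", "sacral dimple", "vertebral pedicle",
  "spinous process", "cranial suture", "parietal eminence", "occipital crest",
  "mastoid antrum", "auditory canal", "optic chiasm", "ciliary margin"
)

#' Simulate a toy HPO-style ontology
#'
#' Deterministically builds a small ontology whose labels are multi-word
#' clinical phrases ("Hypoplastic femoral neck") drawn from disjoint
#' per-term vocabulary: no adjective or anatomical structure is reused
#' across terms. Used throughout the test suite in place of the full HPO
#' release. The lexical disjointness underwrites the synthetic corpus
#' generator's separability guarantee — a sentence built around a term's
#' label or synonym remains attributable to that term by character n-gram
#' similarity.
#'
#' @param n_terms Number of terms (1 to 60).
#' @param seed Integer seed controlling which adjective/structure pairings
#'   are drawn.
#' @param n_synonyms Synonyms per term, 0 or 1. The synonym is the
#'   reordered form of the label ("Femoral neck, hypoplastic").
#' @param prop_obsolete Proportion of terms flagged obsolete (rounded down).
#' @return An [new_ontology()] tibble.
#' @examples
#' simulate_ontology(3, seed = 1)
#' @export
simulate_ontology <- function(n_terms, seed = 1L, n_synonyms = 1L,
                              prop_obsolete = 0) {
  stopifnot(n_terms >= 1, n_synonyms %in% c(0L, 1L),
            prop_obsolete >= 0, prop_obsolete <= 1)
  n_max <- min(length(.pheno_adjectives), length(.pheno_structures))
  if (n_terms > n_max) {
    abort_validation(sprintf("at most %d synthetic terms available", n_max))
  }
  withr::with_seed(seed, {
    desc <- sample(.pheno_adjectives, n_terms)
    anat <- sample(.pheno_structures, n_terms)
  })
  cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
  labels <- cap(paste(desc, anat))
  synonyms <- if (n_synonyms == 1L) {
    purrr::map2(anat, desc, ~ paste0(cap(.x), ", ", .y))
  } else {
    rep(list(character()), n_terms)
  }
  n_obs <- floor(prop_obsolete * n_terms)
  new_ontology(tibble(
    term_id = sprintf("HP:%07d", seq_len(n_terms)),
    label = labels,
    definition = paste0("A structural anomaly characterized by ",
                        tolower(labels), "."),
    comments = NA_character_,
    synonyms = synonyms,
    is_obsolete = seq_len(n_terms) <= n_obs
  ), source_format = "synthetic")
}

#' @export
print.hpo_ontology <- function(x, ...) {
  n_obs <- if ("is_obsolete" %in% names(x)) sum(x$is_obsolete) else 0L
  cat(sprintf("<hpo_ontology> %d terms (%d obsolete), source: %s [%s]\n",
              nrow(x), n_obs,
              attr(x, "source_path") %||% "<none>",
              attr(x, "source_format") %||% "?"))
  NextMethod()
}
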