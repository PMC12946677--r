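# Independent oracles and random-fixture builders used across the suite.
# The oracles deliberately re-derive keywords and joins with plain loops and
# base string ops so they share no code path with the package internals.

# keyword computed from first principles: lowercase, split on non-alnum,
# sort tokens by their zero-padded code-point sequence, concatenate
oracle_keyword <- function(label) {
  toks <- unlist(strsplit(tolower(label), "[^[:alnum:]]+"))
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return("")
  codepoint_key <- vapply(toks, function(t) {
    paste(sprintf("%06d", utf8ToInt(t)), collapse = "")
  }, "", USE.NAMES = FALSE)
  paste(toks[order(codepoint_key)], collapse = "")
}

oracle_term_keywords <- function(term) {
  texts <- c(term$label, vapply(term$synonyms, function(s) s$text, ""))
  kw <- unique(vapply(texts, oracle_keyword, "", USE.NAMES = FALSE))
  kw[nzchar(kw)]
}

# brute-force all-pairs lexical comparison of keyword sets
oracle_lexical_match <- function(source, target) {
  tkw_all <- lapply(target$terms, oracle_term_keywords)
  rows <- list()
  for (sid in names(source$terms)) {
    s <- source$terms[[sid]]
    if (s$obsolete) next
    skw <- oracle_term_keywords(s)
    for (tid in names(target$terms)) {
      t <- target$terms[[tid]]
      if (t$obsolete) next
      common <- intersect(skw, tkw_all[[tid]])
      if (length(common)) {
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = sid, target_id = tid, tally = length(common),
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, c(rows, list(data.frame(
    source_id = character(), target_id = character(), tally = integer(),
    stringsAsFactors = FALSE))))
  df[order(df$source_id, df$target_id, method = "radix"), , drop = FALSE]
}

# brute-force triple join (association x trait x qualifying mapping)
oracle_translation_triples <- function(assoc, set, target_prefix,
                                       allowed_predicates = "skos:exactMatch") {
  acc <- accepted_records(set)
  triples <- character()
  for (r in seq_len(nrow(assoc))) {
    traits <- c(assoc$trait_ids[[r]], assoc$background_trait_ids[[r]])
    for (tr in traits) {
      for (m in seq_len(nrow(acc))) {
        if (acc$subject_id[m] == tr &&
            sub(":.*", "", acc$object_id[m]) == target_prefix &&
            acc$predicate[m] %in% allowed_predicates) {
          triples <- c(triples, paste(assoc$qtl_name[r], acc$object_id[m],
                                      tr, sep = "\r"))
        }
      }
    }
  }
  unique(triples)
}

# random ontology over a shared small vocabulary (high collision chance),
# with optional synonyms and obsolete terms
random_ontology <- function(n, prefix, pool, p_synonym = 0.3,
                            p_obsolete = 0.05) {
  terms <- lapply(seq_len(n), function(i) {
    lab <- paste(sample(pool, sample(1:3, 1), replace = TRUE), collapse = " ")
    syns <- if (stats::runif(1) < p_synonym) {
      list(synonym(paste(sample(pool, 2), collapse = " "),
                   sample(c("EXACT", "BROAD", "NARROW", "RELATED"), 1)))
    } else {
      list()
    }
    ontology_term(sprintf("%s:%05d", prefix, i), lab, synonyms = syns,
                  obsolete = stats::runif(1) < p_obsolete)
  })
  ontology(terms, prefix = prefix)
}

# mapping set shaped like published per-ontology mapping tallies:
# per prefix, `auto` subjects justified by lexical automation and
# `total - auto` by manual curation, each mapped to one target term
tally_shaped_mapping_set <- function(counts) {
  parts <- lapply(names(counts), function(p) {
    total <- counts[[p]][1L]
    auto <- counts[[p]][2L]
    data.frame(
      subject_id = sprintf("EFO:%s%07d", p, seq_len(total)),
      object_id = sprintf("%s:%07d", p, seq_len(total)),
      justification = rep(c("LEXICAL_AUTOMATED", "MANUAL_CURATION"),
                          c(auto, total - auto)),
      scope = "EXACT", status = "ACCEPTED", curator = "c", editor = "e",
      stringsAsFactors = FALSE)
  })
  set <- mapping_set(mapping_set_id = "https://example.org/mappings/tallies")
  add_mappings(set, do.call(rbind, parts))
}

# small curated set used by gwas/sssom tests: three targets for one subject
demo_mapping_set <- function() {
  set <- mapping_set(
    mapping_set_id = "https://example.org/mappings/demo",
    curie_map = list(EFO = "http://www.ebi.ac.uk/efo/EFO_",
                     DOID = "http://purl.obolibrary.org/obo/DOID_",
                     HP = "http://purl.obolibrary.org/obo/HP_",
                     VT = "http://purl.obolibrary.org/obo/VT_"))
  add_mappings(set, data.frame(
    subject_id = rep("EFO:0004325", 3),
    subject_label = rep("systolic blood pressure", 3),
    object_id = c("DOID:10763", "HP:0004421", "VT:0000183"),
    object_label = c("hypertension", "elevated systolic blood pressure",
                     "systolic blood pressure trait"),
    scope = "EXACT", justification = "LEXICAL_AUTOMATED",
    status = "ACCEPTED", curator = "c1", editor = "e1",
    stringsAsFactors = FALSE))
}

word_pool <- c("blood", "pressure", "systolic", "diastolic", "glucose",
               "serum", "heart", "rate", "mass", "index")
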