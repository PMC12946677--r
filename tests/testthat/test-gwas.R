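gwas_header <- paste("SNPS", "DISEASE/TRAIT", "MAPPED_TRAIT_URI",
                     "MAPPED_BACKGROUND_TRAIT_URI", "P-VALUE", sep = "\t")

test_that("association rows parse with URI-tail normalization", {
  txt <- paste(gwas_header,
               paste("rs699", "systolic blood pressure",
                     "http://www.ebi.ac.uk/efo/EFO_0004325", "", "2E-11",
                     sep = "\t"),
               paste("rs1234", "obesity and diabetes",
                     "http://www.ebi.ac.uk/efo/EFO_0001073|http://www.ebi.ac.uk/efo/EFO_0000400",
                     "http://www.ebi.ac.uk/efo/EFO_0004340", "1E-8",
                     sep = "\t"),
               sep = "\n")
  a <- parse_gwas_associations(text = txt)
  expect_equal(nrow(a), 2L)
  expect_equal(a$trait_ids[[1]], "EFO:0004325")
  expect_equal(a$trait_ids[[2]], c("EFO:0001073", "EFO:0000400"))
  expect_equal(a$background_trait_ids[[2]], "EFO:0004340")
  expect_equal(a$qtl_name, c("GWAS1_H", "GWAS2_H"))
  expect_equal(attr(a, "n_skipped"), 0L)

  # header-only file -> zero associations
  expect_equal(nrow(parse_gwas_associations(text = gwas_header)), 0L)

  # rows without a parseable trait URI are skipped with a warning
  bad <- paste(gwas_header,
               "rs1\ttrait\t\t\t1E-5",
               "rs2\tok trait\thttp://www.ebi.ac.uk/efo/EFO_0000001\t\t1E-5",
               sep = "\n")
  expect_warning(a2 <- parse_gwas_associations(text = bad), "skipped")
  expect_equal(nrow(a2), 1L)
  expect_equal(attr(a2, "n_skipped"), 1L)

  expect_error(parse_gwas_associations(text = "SNPS\tP-VALUE\nrs1\t1"),
               "MAPPED_TRAIT_URI")
})

test_that("one EFO annotation fans out across mapped target ontologies", {
  set <- demo_mapping_set()
  txt <- paste(gwas_header,
               paste("rs1013451", "systolic blood pressure",
                     "http://www.ebi.ac.uk/efo/EFO_0004325", "", "3E-15",
                     sep = "\t"),
               sep = "\n")
  a <- parse_gwas_associations(text = txt)
  ann <- do.call(rbind, lapply(c("DOID", "HP", "VT"), function(p) {
    translate_annotations(a, set, p)
  }))
  expect_equal(nrow(ann), 3L)
  expect_setequal(ann$term_id, c("DOID:10763", "HP:0004421", "VT:0000183"))
  expect_equal(unique(ann$source_term_id), "EFO:0004325")
  expect_equal(unique(ann$mapping_predicate), "skos:exactMatch")
  expect_false(any(ann$background))
})

test_that("translation respects predicates, fans out and keeps provenance", {
  set <- mapping_set()
  set <- add_mappings(set, data.frame(
    subject_id = c("EFO:1", "EFO:1", "EFO:2"),
    object_id = c("DOID:1", "DOID:2", "DOID:3"),
    object_label = c("d one", "d two", "d three"),
    scope = c("EXACT", "EXACT", "NARROW"),
    curator = "c", editor = "e", stringsAsFactors = FALSE))
  txt <- paste(gwas_header,
               "rs1\tt one\thttp://x.org/EFO_1\t\t1E-9",
               "rs2\tt two\thttp://x.org/EFO_2\t\t1E-9",
               sep = "\n")
  a <- parse_gwas_associations(text = txt)

  # trait with two accepted exact mappings -> two annotations
  ann <- translate_annotations(a, set, "DOID")
  expect_equal(nrow(ann), 2L)
  expect_setequal(ann$term_id, c("DOID:1", "DOID:2"))

  # non-exact mapping excluded by default, included when allowed
  expect_false("DOID:3" %in% ann$term_id)
  wide <- translate_annotations(a, set, "DOID",
                                allowed_predicates = c("skos:exactMatch",
                                                       "skos:broadMatch"))
  expect_true("DOID:3" %in% wide$term_id)

  # association whose only trait has no accepted mapping -> empty
  lone <- parse_gwas_associations(
    text = paste(gwas_header, "rs3\tx\thttp://x.org/EFO_99\t\t1E-9", sep = "\n"))
  expect_equal(nrow(translate_annotations(lone, set, "DOID")), 0L)
})

test_that("background traits translate flagged and unmapped terms are logged", {
  set <- demo_mapping_set()
  txt <- paste(gwas_header,
               paste("rs1", "a", "http://x.org/EFO_0009999",
                     "http://www.ebi.ac.uk/efo/EFO_0004325", "1E-9", sep = "\t"),
               sep = "\n")
  a <- parse_gwas_associations(text = txt)
  ann <- translate_annotations(a, set, "DOID")
  expect_equal(nrow(ann), 1L)
  expect_true(ann$background)   # survives translation unchanged
  # background-only unmapped traits are monitored too
  expect_equal(detect_unmapped_terms(a, set), "EFO:0009999")
  # all traits mapped -> empty log
  mapped_only <- parse_gwas_associations(
    text = paste(gwas_header,
                 "rs2\tb\thttp://x.org/EFO_0004325\t\t1E-9", sep = "\n"))
  expect_equal(detect_unmapped_terms(mapped_only, set), character())
})

test_that("translation matches the brute-force triple join and partitions", {
  fx <- gen_ontology_pair(fixture_spec(n_exact_label = 6, n_permuted = 3,
                                       n_synonym_only = 3, n_xref_only = 2,
                                       n_distractor_target = 8, seed = 13))
  set <- add_mappings(mapping_set(), data.frame(
    subject_id = fx$truth$source_id, object_id = fx$truth$target_id,
    scope = "EXACT", justification = "LEXICAL_AUTOMATED",
    curator = "c", editor = "e", stringsAsFactors = FALSE))
  tsv <- gen_associations(fx$source, n_assoc = 40, frac_unmapped = 0.2,
                          frac_background = 0.3, seed = 17)
  a <- parse_gwas_associations(text = tsv)

  ann <- translate_annotations(a, set, "DOID")
  triples <- oracle_translation_triples(a, set, "DOID")
  expect_equal(nrow(ann), length(triples))   # conservation after dedup
  expect_setequal(paste(ann$qtl_name, ann$term_id, ann$source_term_id,
                        sep = "\r"), triples)

  # partition: every input trait id is translated or logged, never both
  traits <- unique(c(unlist(a$trait_ids), unlist(a$background_trait_ids)))
  translated <- unique(ann$source_term_id)
  unmapped <- detect_unmapped_terms(a, set)
  expect_length(intersect(translated, unmapped), 0L)
  expect_setequal(c(translated, unmapped), traits)
})
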