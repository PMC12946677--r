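test_that("scope maps to its SKOS predicate, crossed for broad/narrow", {
  expect_equal(scope_to_predicate("EXACT"), "skos:exactMatch")
  expect_equal(scope_to_predicate("RELATED"), "skos:relatedMatch")
  expect_equal(scope_to_predicate("NARROW"), "skos:broadMatch")
  expect_equal(scope_to_predicate("BROAD"), "skos:narrowMatch")
  expect_error(scope_to_predicate("CLOSE"), "invalid")
  # predicate_to_scope inverts, unknown degrades to RELATED
  for (s in c("EXACT", "BROAD", "NARROW", "RELATED")) {
    expect_equal(predicate_to_scope(scope_to_predicate(s)), s)
  }
  expect_equal(predicate_to_scope("skos:closeMatch"), "RELATED")
})

lex_cand <- list(source_id = "EFO:0000001", source_label = "heart attack",
                 target_id = "DOID:0000001",
                 target_label = "myocardial infarction", method = "LEXICAL")

test_that("decide produces PROPOSED records with the right justification", {
  s <- decide(mapping_set(), lex_cand, "EXACT", "alice")
  r <- s$records
  expect_equal(r$status, "PROPOSED")
  expect_equal(r$justification, "LEXICAL_AUTOMATED")
  expect_equal(r$predicate, "skos:exactMatch")
  expect_equal(r$curator, "alice")

  # hand-entered pair -> MANUAL_CURATION, BROAD -> skos:narrowMatch
  s2 <- decide(mapping_set(),
               manual_candidate("EFO:0000002", "DOID:0000002"), "BROAD", "bob")
  expect_equal(s2$records$justification, "MANUAL_CURATION")
  expect_equal(s2$records$predicate, "skos:narrowMatch")

  # same pair decided twice is rejected by the uniqueness invariant
  expect_error(decide(s, lex_cand, "EXACT", "alice"), "already exists")
})

test_that("review implements the two-pass accept/reject/change workflow", {
  s <- decide(mapping_set(), lex_cand, "EXACT", "alice")

  acc <- review(s, "EFO:0000001", "DOID:0000001", "ACCEPT", "bob")
  expect_equal(acc$records$status, "ACCEPTED")
  expect_equal(acc$records$editor, "bob")

  rej <- review(s, "EFO:0000001", "DOID:0000001", "REJECT", "bob")
  expect_equal(rej$records$status, "REJECTED")
  expect_equal(nrow(accepted_records(rej)), 0L)  # excluded from export

  # CHANGE rejects the original with a linking comment and accepts a
  # replacement whose predicate follows the new scope
  chg <- review(s, "EFO:0000001", "DOID:0000001", "CHANGE", "bob",
                new_scope = "NARROW")
  expect_equal(nrow(chg$records), 2L)
  expect_equal(chg$records$status, c("REJECTED", "ACCEPTED"))
  expect_match(chg$records$comment[1], "changed to")
  expect_match(chg$records$comment[2], "replaces")
  expect_equal(chg$records$predicate[2], "skos:broadMatch")
  expect_equal(chg$records$curator[2], "alice")  # provenance of pass 1 kept
  expect_equal(chg$records$editor[2], "bob")

  # reviewing a non-PROPOSED record fails; empty editor fails
  expect_error(review(acc, "EFO:0000001", "DOID:0000001", "ACCEPT", "bob"),
               "no PROPOSED")
  expect_error(review(s, "EFO:0000001", "DOID:0000001", "ACCEPT", ""),
               "editor")
  expect_error(review(s, "EFO:0000001", "DOID:0000001", "CHANGE", "bob"),
               "new_object_id and/or new_scope")
})

test_that("invariants hold after arbitrary decide/review sequences", {
  set.seed(23)
  s <- mapping_set()
  for (i in 1:30) {
    cand <- list(source_id = sprintf("EFO:%04d", i), source_label = "s",
                 target_id = sprintf("DOID:%04d", sample(1:40, 1)),
                 target_label = "t",
                 method = sample(c("LEXICAL", "XREF", "MANUAL"), 1))
    s <- tryCatch(decide(s, cand, sample(c("EXACT", "BROAD", "NARROW",
                                           "RELATED"), 1), "alice"),
                  error = function(e) s)
  }
  prop <- s$records[s$records$status == "PROPOSED", ]
  for (i in seq_len(nrow(prop))) {
    s <- review(s, prop$subject_id[i], prop$object_id[i],
                sample(c("ACCEPT", "REJECT", "CHANGE"), 1), "bob",
                new_scope = "RELATED")
  }
  acc <- accepted_records(s)
  expect_true(all(nzchar(acc$curator) & nzchar(acc$editor)))
  expect_equal(s$records$predicate, scope_to_predicate(s$records$scope))
  expect_false(anyDuplicated(acc[c("subject_id", "object_id")]) > 0)
})

test_that("bulk add validates statuses, editors and pair uniqueness", {
  df <- data.frame(subject_id = c("EFO:1", "EFO:2"),
                   object_id = c("DOID:1", "DOID:2"),
                   justification = "LEXICAL_AUTOMATED",
                   curator = "c", editor = "e", stringsAsFactors = FALSE)
  s <- add_mappings(mapping_set(), df)
  expect_equal(nrow(accepted_records(s)), 2L)
  expect_error(add_mappings(s, df[1, ]), "duplicate")
  bad <- df; bad$editor <- ""
  expect_error(add_mappings(mapping_set(), bad), "editor")
  bad2 <- df; bad2$justification <- "GUESSWORK"
  expect_error(add_mappings(mapping_set(), bad2), "justification")
})

test_that("the decision journal records one row per event", {
  s <- decide(mapping_set(), lex_cand, "EXACT", "alice")
  s <- review(s, "EFO:0000001", "DOID:0000001", "ACCEPT", "bob")
  expect_equal(s$journal$event, c("DECIDE", "ACCEPT"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_journal(s, path)
  expect_equal(nrow(utils::read.delim(path)), 2L)
})
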