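## scope -> SKOS predicate. Scope is recorded from the TARGET term's
## perspective (the source term is added as a synonym of the target), so a
## NARROW synonym means the subject is narrower than the object, i.e.
## subject skos:broadMatch object.
SCOPE_PREDICATES <- c(EXACT = "skos:exactMatch",
                      RELATED = "skos:relatedMatch",
                      NARROW = "skos:broadMatch",
                      BROAD = "skos:narrowMatch")

JUSTIFICATION_SEMAPV <- c(LEXICAL_AUTOMATED = "semapv:LexicalMatching",
                          MANUAL_CURATION = "semapv:ManualMappingCuration")

#' Translate a synonym scope to its SKOS match predicate
#'
#' EXACT maps to `skos:exactMatch`, RELATED to `skos:relatedMatch`, NARROW
#' to `skos:broadMatch` and BROAD to `skos:narrowMatch`. The latter two are
#' crossed because the scope is assigned from the target term's perspective
#' while the predicate relates subject to object.
#'
#' @param scope One of `"EXACT"`, `"BROAD"`, `"NARROW"`, `"RELATED"`.
#' @return The predicate CURIE.
#' @export
#' @examples
#' scope_to_predicate("NARROW")  # "skos:broadMatch"
scope_to_predicate <- function(scope) {
  scope <- toupper(as.character(scope))
  bad <- !scope %in% SYNONYM_SCOPES
  if (any(bad)) {
    stop("invalid synonym scope: ", paste(scope[bad], collapse = ", "),
         call. = FALSE)
  }
  unname(SCOPE_PREDICATES[scope])
}

#' Translate a SKOS predicate back to a synonym scope
#'
#' Inverse of [scope_to_predicate()]; unknown predicates degrade to
#' `"RELATED"` rather than being dropped.
#'
#' @param predicate Predicate CURIE(s).
#' @return Scope value(s).
#' @export
predicate_to_scope <- function(predicate) {
  inv <- stats::setNames(names(SCOPE_PREDICATES), SCOPE_PREDICATES)
  out <- unname(inv[as.character(predicate)])
  out[is.na(out)] <- "RELATED"
  out
}

empty_mapping_records <- function() {
  data.frame(subject_id = character(), subject_label = character(),
             object_id = character(), object_label = character(),
             scope = character(), predicate = character(),
             justification = character(), status = character(),
             curator = character(), editor = character(),
             comment = character(), stringsAsFactors = FALSE)
}

empty_journal <- function() {
  data.frame(event_no = integer(), event = character(),
             subject_id = character(), object_id = character(),
             actor = character(), detail = character(),
             stringsAsFactors = FALSE)
}

#' Create an empty mapping set
#'
#' A mapping set carries curated mapping records plus the metadata needed
#' for SSSOM exchange (a mapping set id, a license notice and a CURIE
#' prefix -> URI base map). Metadata keys and the curie map are kept in
#' sorted order so serialization is canonical.
#'
#' @param mapping_set_id Identifier URI/string for the set.
#' @param curie_map Named list/character of prefix -> URI base; `skos` and
#'   `semapv` are always included.
#' @param license License notice; defaults to a CC0 placeholder.
#' @param ... Further metadata key/value pairs.
#' @return An object of class `"mapping_set"`.
#' @export
mapping_set <- function(mapping_set_id = "https://example.org/mappings/default",
                        curie_map = list(), license = "https://creativecommons.org/publicdomain/zero/1.0/",
                        ...) {
  cm <- c(as.list(curie_map),
          list(skos = "http://www.w3.org/2004/02/skos/core#",
               semapv = "https://w3id.org/semapv/vocab/"))
  cm <- cm[!duplicated(names(cm))]
  cm <- cm[order(names(cm), method = "radix")]
  meta <- c(list(mapping_set_id = mapping_set_id, license = license,
                 curie_map = cm), list(...))
  meta <- meta[order(names(meta), method = "radix")]
  structure(list(metadata = meta, records = empty_mapping_records(),
                 journal = empty_journal(), extra_columns = NULL),
            class = "mapping_set")
}

#' @export
print.mapping_set <- function(x, ...) {
  cat(sprintf("<mapping_set> %s: %d record(s) [%s]\n",
              x$metadata$mapping_set_id, nrow(x$records),
              paste(names(table(x$records$status)), table(x$records$status),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

## pair uniqueness among live (non-REJECTED) records; REJECTED pairs may be
## re-proposed (e.g. by a CHANGE that only alters the scope)
assert_pair_free <- function(set, subject_id, object_id) {
  live <- set$records$status != "REJECTED"
  clash <- live & set$records$subject_id == subject_id &
    set$records$object_id == object_id
  if (any(clash)) {
    stop("mapping for pair (", subject_id, ", ", object_id,
         ") already exists", call. = FALSE)
  }
}

log_event <- function(set, event, subject_id, object_id, actor, detail = "") {
  set$journal <- rbind(set$journal, data.frame(
    event_no = nrow(set$journal) + 1L, event = event,
    subject_id = subject_id, object_id = object_id, actor = actor,
    detail = detail, stringsAsFactors = FALSE))
  set
}

#' Record a curator decision over a match candidate
#'
#' Turns a candidate (a row of the matcher output, or a hand-entered pair
#' built with [manual_candidate()]) into a PROPOSED mapping record. The
#' justification is `LEXICAL_AUTOMATED` when the candidate came from either
#' matcher (method LEXICAL or XREF) and `MANUAL_CURATION` otherwise; the
#' predicate is always derived from the scope via [scope_to_predicate()].
#'
#' @param set A [mapping_set()].
#' @param candidate A one-row data frame or list with `source_id`,
#'   `source_label`, `target_id`, `target_label` and optionally `method`.
#' @param scope Synonym scope assigned by the curator.
#' @param curator Curator identifier.
#' @return The updated mapping set (new record has status `PROPOSED`).
#' @export
decide <- function(set, candidate, scope, curator) {
  stopifnot(inherits(set, "mapping_set"))
  cand <- as.list(candidate)
  sid <- as.character(cand$source_id)[1L]
  oid <- as.character(cand$target_id)[1L]
  if (!length(sid) || !length(oid) || is.na(sid) || is.na(oid)) {
    stop("candidate must carry source_id and target_id", call. = FALSE)
  }
  assert_pair_free(set, sid, oid)
  scope <- toupper(scope)
  method <- as.character(cand$method %||% "")[1L]
  just <- if (isTRUE(method %in% c("LEXICAL", "XREF"))) {
    "LEXICAL_AUTOMATED"
  } else {
    "MANUAL_CURATION"
  }
  rec <- data.frame(
    subject_id = sid,
    subject_label = as.character(cand$source_label %||% "")[1L],
    object_id = oid,
    object_label = as.character(cand$target_label %||% "")[1L],
    scope = scope, predicate = scope_to_predicate(scope),
    justification = just, status = "PROPOSED",
    curator = as.character(curator), editor = "", comment = "",
    stringsAsFactors = FALSE)
  set$records <- rbind(set$records, rec)
  log_event(set, "DECIDE", sid, oid, curator, paste0("scope=", scope))
}

#' Build a hand-entered candidate for manual curation
#'
#' @param source_id,object_id Subject and object CURIEs.
#' @param source_label,object_label Labels (optional).
#' @return A list usable as the `candidate` argument of [decide()]; its
#'   justification will be `MANUAL_CURATION`.
#' @export
manual_candidate <- function(source_id, object_id, source_label = "",
                             object_label = "") {
  list(source_id = normalize_curie(source_id), source_label = source_label,
       target_id = normalize_curie(object_id), target_label = object_label,
       method = "MANUAL")
}

#' Second-pass editor review of a proposed mapping
#'
#' Implements the two-step curation workflow: a second curator/editor
#' accepts, rejects, or changes a PROPOSED mapping. `ACCEPT` marks the
#' record ACCEPTED and records the editor (every accepted mapping therefore
#' carries both a curator and an editor). `REJECT` marks it REJECTED.
#' `CHANGE` rejects the original with a comment linking its replacement and
#' adds a new record with the replacement object and/or scope, immediately
#' accepted by the editor. An editor equal to the original curator is
#' permitted but noted in the journal.
#'
#' @param set A [mapping_set()].
#' @param subject_id,object_id Pair identifying the PROPOSED record.
#' @param action One of `"ACCEPT"`, `"REJECT"`, `"CHANGE"`.
#' @param editor Editor identifier (non-empty).
#' @param new_object_id,new_object_label,new_scope Replacement values,
#'   required (at least one of id/scope) for `CHANGE`.
#' @return The updated mapping set.
#' @export
review <- function(set, subject_id, object_id, action, editor,
                   new_object_id = NULL, new_object_label = NULL,
                   new_scope = NULL) {
  stopifnot(inherits(set, "mapping_set"))
  action <- toupper(match.arg(toupper(action), c("ACCEPT", "REJECT", "CHANGE")))
  editor <- as.character(editor)
  if (!length(editor) || !nzchar(editor)) {
    stop("review requires a non-empty editor", call. = FALSE)
  }
  i <- which(set$records$subject_id == subject_id &
             set$records$object_id == object_id &
             set$records$status == "PROPOSED")
  if (length(i) != 1L) {
    stop("no PROPOSED record for pair (", subject_id, ", ", object_id, ")",
         call. = FALSE)
  }
  if (identical(editor, set$records$curator[i])) {
    set <- log_event(set, "NOTE", subject_id, object_id, editor,
                     "editor equals curator")
  }
  if (action == "ACCEPT") {
    set$records$status[i] <- "ACCEPTED"
    set$records$editor[i] <- editor
    return(log_event(set, "ACCEPT", subject_id, object_id, editor))
  }
  if (action == "REJECT") {
    set$records$status[i] <- "REJECTED"
    set$records$editor[i] <- editor
    return(log_event(set, "REJECT", subject_id, object_id, editor))
  }
  ## CHANGE: reject original, add replacement, accept it
  if (is.null(new_object_id) && is.null(new_scope)) {
    stop("CHANGE requires new_object_id and/or new_scope", call. = FALSE)
  }
  old <- set$records[i, ]
  oid2 <- if (is.null(new_object_id)) old$object_id else normalize_curie(new_object_id)
  scope2 <- toupper(if (is.null(new_scope)) old$scope else new_scope)
  set$records$status[i] <- "REJECTED"
  set$records$editor[i] <- editor
  set$records$comment[i] <- paste0("changed to (", old$subject_id, ", ", oid2,
                                   ", ", scope2, ") on review")
  set <- log_event(set, "CHANGE", subject_id, object_id, editor,
                   paste0("-> ", oid2, " scope=", scope2))
  assert_pair_free(set, old$subject_id, oid2)
  rec <- data.frame(
    subject_id = old$subject_id, subject_label = old$subject_label,
    object_id = oid2,
    object_label = as.character(new_object_label %||% old$object_label),
    scope = scope2, predicate = scope_to_predicate(scope2),
    justification = old$justification, status = "ACCEPTED",
    curator = old$curator, editor = editor,
    comment = paste0("replaces (", old$subject_id, ", ", old$object_id, ")"),
    stringsAsFactors = FALSE)
  set$records <- rbind(set$records, rec)
  log_event(set, "ACCEPT", old$subject_id, oid2, editor, "via CHANGE")
}

#' Bulk-add mapping records
#'
#' Vectorized path for loading many curated mappings at once (e.g. tallies
#' keyed to published mapping counts, or externally curated sets). Predicate
#' is filled from scope; pair uniqueness among non-REJECTED records is
#' enforced; ACCEPTED rows must carry a non-empty editor.
#'
#' @param set A [mapping_set()].
#' @param df Data frame with at least `subject_id`, `object_id`; optional
#'   `subject_label`, `object_label`, `scope` (default `EXACT`),
#'   `justification` (default `MANUAL_CURATION`), `status` (default
#'   `ACCEPTED`), `curator`, `editor`, `comment`.
#' @return The updated mapping set.
#' @export
add_mappings <- function(set, df) {
  stopifnot(inherits(set, "mapping_set"), is.data.frame(df))
  n <- nrow(df)
  if (!n) return(set)
  col <- function(name, default) {
    if (name %in% names(df)) as.character(df[[name]]) else rep(default, n)
  }
  scope <- toupper(col("scope", "EXACT"))
  status <- toupper(col("status", "ACCEPTED"))
  just <- col("justification", "MANUAL_CURATION")
  if (!all(just %in% names(JUSTIFICATION_SEMAPV))) {
    stop("unknown justification value(s)", call. = FALSE)
  }
  editor <- col("editor", "editor")
  if (any(status == "ACCEPTED" & !nzchar(editor))) {
    stop("ACCEPTED records require a non-empty editor", call. = FALSE)
  }
  rec <- data.frame(
    subject_id = normalize_curie(df$subject_id),
    subject_label = col("subject_label", ""),
    object_id = normalize_curie(df$object_id),
    object_label = col("object_label", ""),
    scope = scope, predicate = scope_to_predicate(scope),
    justification = just, status = status,
    curator = col("curator", "curator"), editor = editor,
    comment = col("comment", ""), stringsAsFactors = FALSE)
  all_rec <- rbind(set$records, rec)
  live <- all_rec[all_rec$status != "REJECTED", c("subject_id", "object_id")]
  if (anyDuplicated(live)) {
    stop("duplicate (subject_id, object_id) pair(s) among non-rejected records",
         call. = FALSE)
  }
  set$records <- all_rec
  set
}

#' Accepted records of a mapping set
#' @param set A [mapping_set()].
#' @return Data frame of records with status `ACCEPTED`, sorted by
#'   (subject_id, object_id).
#' @export
accepted_records <- function(set) {
  r <- set$records[set$records$status == "ACCEPTED", , drop = FALSE]
  r <- r[order(r$subject_id, r$object_id, method = "radix"), , drop = FALSE]
  row.names(r) <- NULL
  r
}

#' Write the decision journal as TSV
#' @param set A [mapping_set()].
#' @param file Path or connection.
#' @return The journal data frame, invisibly.
#' @export
write_journal <- function(set, file) {
  utils::write.table(set$journal, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(set$journal)
}
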