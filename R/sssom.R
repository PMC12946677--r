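SSSOM_COLUMNS <- c("subject_id", "subject_label", "predicate_id", "object_id",
                   "object_label", "mapping_justification", "author_id",
                   "reviewer_id", "comment")

#' Serialize a mapping set as SSSOM TSV
#'
#' Emits the set metadata as a leading block of `#`-prefixed YAML lines
#' (mapping_set_id, license, curie_map, any further keys), then a TSV header
#' and one row per exported record, sorted by (subject_id, object_id).
#' Internal justification values are serialized to the semapv vocabulary
#' (`LEXICAL_AUTOMATED` -> `semapv:LexicalMatching`, `MANUAL_CURATION` ->
#' `semapv:ManualMappingCuration`). By default only ACCEPTED records are
#' exported, matching the convention that published files represent
#' validated mappings.
#'
#' @param set A [mapping_set()].
#' @param file Path or connection; if `NULL` the text is returned only.
#' @param statuses Statuses to export (default `"ACCEPTED"`).
#' @return The SSSOM text, invisibly when written to `file`.
#' @export
write_sssom <- function(set, file = NULL, statuses = "ACCEPTED") {
  stopifnot(inherits(set, "mapping_set"))
  r <- set$records[set$records$status %in% statuses, , drop = FALSE]
  r <- r[order(r$subject_id, r$object_id, method = "radix"), , drop = FALSE]

  used <- unique(curie_prefix(c(r$subject_id, r$object_id, r$predicate,
                                unname(JUSTIFICATION_SEMAPV[r$justification]))))
  known <- toupper(names(set$metadata$curie_map))
  missing <- setdiff(toupper(used), known)
  if (length(missing)) {
    stop("prefix(es) missing from curie_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  meta_yaml <- strsplit(yaml::as.yaml(set$metadata), "\n", fixed = TRUE)[[1L]]
  header <- paste0("# ", meta_yaml)
  body <- c(paste(SSSOM_COLUMNS, collapse = "\t"),
            if (nrow(r)) {
              paste(r$subject_id, r$subject_label, r$predicate, r$object_id,
                    r$object_label,
                    unname(JUSTIFICATION_SEMAPV[r$justification]),
                    r$curator, r$editor, r$comment, sep = "\t")
            })
  out <- c(header, body)
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Parse an SSSOM TSV mapping set
#'
#' Inverse of [write_sssom()] on files this package wrote. External files
#' are accepted too: unknown columns are preserved in the set's
#' `extra_columns` field, unknown justification strings map to
#' `MANUAL_CURATION` with the original string kept in the comment, and the
#' synonym scope is recovered from the predicate (unknown predicates degrade
#' to RELATED). All records read from a published file are marked ACCEPTED.
#'
#' @param file Path to an SSSOM TSV, optionally with a `#`-prefixed YAML
#'   metadata block.
#' @param text Alternatively, the SSSOM text itself.
#' @return A [mapping_set()].
#' @export
read_sssom <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  is_meta <- grepl("^#", lines)
  meta <- list()
  if (any(is_meta)) {
    meta_txt <- paste(sub("^#[ ]?", "", lines[is_meta]), collapse = "\n")
    meta <- tryCatch(yaml::yaml.load(meta_txt), error = function(e) list())
    if (!is.list(meta)) meta <- list()
  }
  body <- lines[!is_meta]
  body <- body[nzchar(body)]
  if (!length(body)) stop("SSSOM file has no header row", call. = FALSE)
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "")
  mandatory <- c("subject_id", "predicate_id", "object_id")
  absent <- setdiff(mandatory, names(df))
  if (length(absent)) {
    stop("SSSOM file missing mandatory column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  getcol <- function(name, default = "") {
    if (name %in% names(df)) df[[name]] else rep(default, nrow(df))
  }
  just_raw <- getcol("mapping_justification")
  inv_just <- stats::setNames(names(JUSTIFICATION_SEMAPV), JUSTIFICATION_SEMAPV)
  just <- unname(inv_just[just_raw])
  comment <- getcol("comment")
  unknown <- is.na(just)
  just[unknown] <- "MANUAL_CURATION"
  keep <- unknown & nzchar(just_raw)
  comment[keep] <- ifelse(nzchar(comment[keep]),
                          paste0(comment[keep], "; justification=", just_raw[keep]),
                          paste0("justification=", just_raw[keep]))

  set <- mapping_set(
    mapping_set_id = meta$mapping_set_id %||% "https://example.org/mappings/imported",
    curie_map = meta$curie_map %||% list(),
    license = meta$license %||% "https://creativecommons.org/publicdomain/zero/1.0/")
  extra_meta <- meta[setdiff(names(meta), c("mapping_set_id", "curie_map", "license"))]
  if (length(extra_meta)) {
    set$metadata <- c(set$metadata, extra_meta)
    set$metadata <- set$metadata[order(names(set$metadata), method = "radix")]
  }
  if (nrow(df)) {
    rec <- data.frame(
      subject_id = normalize_curie(df$subject_id),
      subject_label = getcol("subject_label"),
      object_id = normalize_curie(df$object_id),
      object_label = getcol("object_label"),
      scope = predicate_to_scope(df$predicate_id),
      predicate = df$predicate_id,
      justification = just, status = "ACCEPTED",
      curator = getcol("author_id"), editor = getcol("reviewer_id"),
      comment = comment, stringsAsFactors = FALSE)
    ## keep the stated predicate only when it is one of ours; otherwise the
    ## scope default (RELATED) re-derives it so the scope/predicate coupling
    ## invariant holds
    known_pred <- rec$predicate %in% SCOPE_PREDICATES
    rec$predicate[!known_pred] <- scope_to_predicate(rec$scope[!known_pred])
    set$records <- rec
  }
  extra_cols <- setdiff(names(df), SSSOM_COLUMNS)
  if (length(extra_cols)) {
    set$extra_columns <- df[extra_cols]
  }
  set
}
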