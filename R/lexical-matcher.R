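#' Build a keyword index over a target ontology
#'
#' Registers, for every non-obsolete target term, each keyword derived from
#' its label (origin `NAME`) and synonyms (origin `SYNONYM`). Keywords shared
#' by several terms map to all of them. Obsolete terms contribute nothing.
#'
#' @param target An [ontology()].
#' @return An object of class `"keyword_index"` with fields `entries` (a
#'   named list: keyword -> data frame of `term_id`, `origin`) and `prefix`.
#' @export
build_index <- function(target) {
  stopifnot(inherits(target, "ontology"))
  kw <- character(); ids <- character(); origin <- character()
  for (id in active_term_ids(target)) {
    t <- target$terms[[id]]
    k <- make_keyword(t$label)
    if (nzchar(k)) {
      kw <- c(kw, k); ids <- c(ids, id); origin <- c(origin, "NAME")
    }
    for (s in t$synonyms) {
      k <- make_keyword(s$text)
      if (nzchar(k)) {
        kw <- c(kw, k); ids <- c(ids, id); origin <- c(origin, "SYNONYM")
      }
    }
  }
  df <- data.frame(keyword = kw, term_id = ids, origin = origin,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  entries <- if (nrow(df)) {
    split(df[c("term_id", "origin")], df$keyword)
  } else {
    list()
  }
  structure(list(entries = entries, prefix = target$prefix),
            class = "keyword_index")
}

#' @export
print.keyword_index <- function(x, ...) {
  cat(sprintf("<keyword_index> prefix=%s keywords=%d\n",
              x$prefix, length(x$entries)))
  invisible(x)
}

#' Match one source term against a keyword index
#'
#' Every keyword of the source term (label and synonyms) is looked up in the
#' index. For each target term hit by at least one source keyword a single
#' candidate is emitted with tally = number of distinct source keywords that
#' hit it and evidence = those keywords. Candidates are ranked by tally
#' descending, ties broken by target id ascending; sources with no hits
#' yield a zero-row table (a tally of 0 is never materialized).
#'
#' @param source A non-obsolete [ontology_term()].
#' @param index A [build_index()] result.
#' @return Data frame with columns `source_id`, `target_id`, `tally`,
#'   `method` (always `"LEXICAL"`), `evidence` (pipe-delimited keywords).
#' @export
match_term <- function(source, index) {
  stopifnot(inherits(source, "onto_term"), inherits(index, "keyword_index"))
  if (source$obsolete) {
    stop("obsolete terms do not participate in matching: ", source$id,
         call. = FALSE)
  }
  kws <- term_keywords(source)
  hit_kw <- character(); hit_id <- character()
  for (k in kws) {
    e <- index$entries[[k]]
    if (!is.null(e)) {
      tids <- unique(e$term_id)
      hit_kw <- c(hit_kw, rep(k, length(tids)))
      hit_id <- c(hit_id, tids)
    }
  }
  if (!length(hit_id)) return(empty_candidates())
  tally <- vapply(split(hit_kw, hit_id), function(v) length(unique(v)), 0L)
  evidence <- vapply(split(hit_kw, hit_id), function(v) {
    paste(sort(unique(v), method = "radix"), collapse = "|")
  }, "")
  ids <- names(tally)
  ord <- order(-tally, ids, method = "radix")
  data.frame(source_id = source$id, target_id = ids[ord],
             tally = as.integer(tally[ord]), method = "LEXICAL",
             evidence = evidence[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

empty_candidates <- function() {
  data.frame(source_id = character(), target_id = character(),
             tally = integer(), method = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

#' Lexically match every source term against a target ontology
#'
#' Runs [match_term()] for each non-obsolete source term (ascending id
#' order) against an index of the target, producing a prioritized candidate
#' table for curators: rows grouped by source id, each group internally
#' ranked by tally then target id.
#'
#' @param source,target [ontology()] objects.
#' @return Data frame with columns `source_id`, `source_label`, `target_id`,
#'   `target_label`, `tally`, `method`, `evidence`.
#' @export
match_ontology <- function(source, target) {
  stopifnot(inherits(source, "ontology"), inherits(target, "ontology"))
  index <- build_index(target)
  parts <- lapply(active_term_ids(source), function(id) {
    match_term(source$terms[[id]], index)
  })
  decorate_candidates(do.call(rbind, c(parts, list(empty_candidates()))),
                      source, target)
}

## add source/target labels to a bare candidate table
decorate_candidates <- function(cand, source, target) {
  cand$source_label <- vapply(cand$source_id, term_label, "", x = source,
                              USE.NAMES = FALSE)
  cand$target_label <- vapply(cand$target_id, term_label, "", x = target,
                              USE.NAMES = FALSE)
  cand[c("source_id", "source_label", "target_id", "target_label",
         "tally", "method", "evidence")]
}

#' Write a candidate table as TSV
#' @param cand Candidate data frame from [match_ontology()],
#'   [xref_match_ontology()] or a concatenation of both.
#' @param file Path or connection.
#' @return `cand`, invisibly.
#' @export
write_candidates <- function(cand, file) {
  utils::write.table(cand, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(cand)
}

#' Read a candidate TSV
#' @param file Path to a TSV written by [write_candidates()].
#' @return Candidate data frame.
#' @export
read_candidates <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE)
  df$tally <- as.integer(df$tally)
  df
}
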