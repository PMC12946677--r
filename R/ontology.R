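#' @keywords internal
"_PACKAGE"

## Synonym scopes form a closed vocabulary shared by the ontology model and
## the curation layer.
SYNONYM_SCOPES <- c("EXACT", "BROAD", "NARROW", "RELATED")

#' Create a scoped synonym
#'
#' A synonym is a free-text alternative name for an ontology term together
#' with a scope describing how close it is to the term's primary meaning:
#' `EXACT` (same meaning), `NARROW` (a subset of the term), `BROAD` (covers
#' more than the term), or `RELATED` (closely associated but not
#' interchangeable).
#'
#' @param text Synonym text; must be non-empty after trimming.
#' @param scope One of `"EXACT"`, `"BROAD"`, `"NARROW"`, `"RELATED"`.
#'   Anything else (including `NA`) falls back to `"RELATED"`.
#' @return A list with elements `text` and `scope`, class `"onto_synonym"`.
#' @export
#' @examples
#' synonym("myocardial infarction", "EXACT")
synonym <- function(text, scope = "RELATED") {
  text <- trimws(as.character(text))
  if (length(text) != 1L || !nzchar(text)) {
    stop("synonym text must be a single non-empty string", call. = FALSE)
  }
  scope <- toupper(as.character(scope))
  if (length(scope) != 1L || is.na(scope) || !scope %in% SYNONYM_SCOPES) {
    scope <- "RELATED"
  }
  structure(list(text = text, scope = scope), class = "onto_synonym")
}

#' Create an ontology term
#'
#' The unit both matchers consume: a CURIE identifier, a primary label,
#' scoped synonyms, database cross-references (XREFs, as CURIEs) and an
#' obsolescence flag. Identifiers and xrefs are normalized to canonical
#' `PREFIX:local` form; duplicate synonyms (same text and scope) and
#' duplicate xrefs are dropped.
#'
#' @param id Term identifier (CURIE or OBO-style URI).
#' @param label Primary name. Required (non-empty) unless `obsolete`.
#' @param synonyms List of [synonym()] objects (bare strings are promoted to
#'   RELATED synonyms).
#' @param xrefs Character vector of CURIEs.
#' @param obsolete Logical; obsolete terms are kept in the model but skipped
#'   by all matching operations.
#' @return An object of class `"onto_term"`.
#' @export
#' @examples
#' ontology_term("EFO:0000001", "heart attack",
#'               synonyms = list(synonym("myocardial infarction", "EXACT")),
#'               xrefs = "MESH:D009203")
ontology_term <- function(id, label = "", synonyms = list(), xrefs = character(),
                          obsolete = FALSE) {
  id <- normalize_curie(id)
  label <- as.character(label)[1L]
  if (is.na(label)) label <- ""
  obsolete <- isTRUE(obsolete)
  if (!obsolete && !nzchar(trimws(label))) {
    stop("non-obsolete term ", id, " must have a non-empty label", call. = FALSE)
  }
  synonyms <- lapply(synonyms, function(s) {
    if (inherits(s, "onto_synonym")) s else synonym(s)
  })
  if (length(synonyms)) {
    key <- vapply(synonyms, function(s) paste0(s$scope, "\r", s$text), "")
    synonyms <- synonyms[!duplicated(key)]
  }
  xrefs <- unique(vapply(as.character(xrefs), normalize_curie, "",
                         USE.NAMES = FALSE))
  structure(
    list(id = id, label = label, synonyms = synonyms, xrefs = xrefs,
         obsolete = obsolete),
    class = "onto_term"
  )
}

#' Create an ontology from a list of terms
#'
#' Terms are keyed (and iterated) by id; ids must be unique. Terms are stored
#' in ascending id order (C-locale) so that serialization is canonical.
#'
#' @param terms List of [ontology_term()] objects.
#' @param prefix Default CURIE prefix; if `NULL`, the most common prefix
#'   among term ids (or `""` for an empty ontology).
#' @return An object of class `"ontology"` with fields `prefix` and `terms`
#'   (a named list).
#' @export
ontology <- function(terms = list(), prefix = NULL) {
  stopifnot(is.list(terms))
  for (t in terms) {
    if (!inherits(t, "onto_term")) {
      stop("all elements of `terms` must be ontology_term objects", call. = FALSE)
    }
  }
  ids <- vapply(terms, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(ids, method = "radix")
  terms <- terms[ord]
  names(terms) <- ids[ord]
  if (is.null(prefix)) {
    prefix <- if (length(ids)) {
      tab <- table(curie_prefix(ids))
      names(tab)[which.max(tab)]
    } else ""
  }
  structure(list(prefix = prefix, terms = terms), class = "ontology")
}

#' @export
length.ontology <- function(x) length(x$terms)

#' @export
print.ontology <- function(x, ...) {
  n_obs <- sum(vapply(x$terms, `[[`, TRUE, "obsolete"))
  cat(sprintf("<ontology> prefix=%s terms=%d (%d obsolete)\n",
              x$prefix, length(x$terms), n_obs))
  invisible(x)
}

#' Look up a term by id
#' @param x An [ontology()].
#' @param id Term CURIE.
#' @return The `onto_term`, or `NULL` if absent.
#' @export
onto_get <- function(x, id) x$terms[[id]]

## ids of terms eligible for matching (non-obsolete)
active_term_ids <- function(x) {
  keep <- !vapply(x$terms, `[[`, TRUE, "obsolete")
  names(x$terms)[keep]
}

term_label <- function(x, id) {
  t <- x$terms[[id]]
  if (is.null(t)) "" else t$label
}
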