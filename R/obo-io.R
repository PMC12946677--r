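#' Parse an OBO flat file into an ontology
#'
#' Reads OBO 1.2/1.4 tag-value text. Only `[Term]` stanzas are modeled;
#' `[Typedef]` and `[Instance]` stanzas, and any tag other than `id`, `name`,
#' `synonym`, `xref` and `is_obsolete`, are ignored without error. Synonym
#' scope is taken from the token following the quoted synonym text
#' (EXACT/BROAD/NARROW/RELATED); a missing or unrecognized token maps to
#' RELATED. The header `ontology:` tag, when present, supplies the default
#' CURIE prefix (upper-cased).
#'
#' @param file Path to an OBO file (UTF-8), or a connection.
#' @param text Alternatively, OBO text as a single string or character
#'   vector of lines.
#' @return An [ontology()].
#' @export
#' @examples
#' o <- parse_obo(text = c("[Term]", "id: EFO:0000001", "name: heart attack",
#'                         'synonym: "myocardial infarction" EXACT []'))
#' length(o)
parse_obo <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  prefix <- NULL
  terms <- list()

  in_term <- FALSE      # inside a [Term] stanza
  in_header <- TRUE     # before the first stanza
  cur <- NULL           # accumulator for the current term stanza
  cur_line <- NA_integer_

  flush_term <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id)) {
      stop("OBO parse error: [Term] stanza starting at line ", cur_line,
           " has no id", call. = FALSE)
    }
    t <- ontology_term(cur$id, cur$name %||% "", synonyms = cur$synonyms,
                       xrefs = cur$xrefs, obsolete = isTRUE(cur$obsolete))
    if (!is.null(terms[[t$id]])) {
      stop("OBO parse error: duplicate term id ", t$id, call. = FALSE)
    }
    terms[[t$id]] <<- t
    cur <<- NULL
  }

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^\\[", line)) {
      flush_term()
      in_header <- FALSE
      in_term <- trimws(line) == "[Term]"
      if (in_term) {
        cur <- list(synonyms = list(), xrefs = character())
        cur_line <- i
      }
      next
    }
    line <- trimws(line)
    if (!nzchar(line)) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0) next
    tag <- substr(line, 1L, m - 1L)
    value <- trimws(substr(line, m + 1L, nchar(line)))

    if (in_header && tag == "ontology") {
      prefix <- toupper(strip_obo_comment(value))
      next
    }
    if (!in_term || is.null(cur)) next

    switch(tag,
      id = { cur$id <- strip_obo_comment(value) },
      name = { cur$name <- strip_obo_comment(value) },
      synonym = {
        syn <- parse_obo_synonym(value)
        if (!is.null(syn)) cur$synonyms <- c(cur$synonyms, list(syn))
      },
      xref = {
        v <- strip_obo_comment(value)
        # drop an optional trailing quoted description: `MESH:D1 "desc"`
        v <- trimws(sub('\\s+".*$', "", v))
        if (nzchar(v)) cur$xrefs <- c(cur$xrefs, v)
      },
      is_obsolete = {
        cur$obsolete <- identical(tolower(strip_obo_comment(value)), "true")
      },
      NULL
    )
  }
  flush_term()
  ontology(terms, prefix = prefix)
}

## strip an unquoted trailing `! comment` from simple tag values
strip_obo_comment <- function(x) trimws(sub("\\s*!.*$", "", x))

## `"text" SCOPE [xrefs]` -> onto_synonym, or NULL when unparseable
parse_obo_synonym <- function(value) {
  m <- regmatches(value,
                  regexec('^"((?:[^"\\\\]|\\\\.)*)"\\s*(.*)$', value, perl = TRUE))[[1]]
  if (length(m) < 2L) return(NULL)
  text <- gsub('\\\\(.)', "\\1", m[2])
  if (!nzchar(trimws(text))) return(NULL)
  trailer <- trimws(m[3])
  tok <- toupper(sub("\\s.*$", "", sub("\\[.*$", "", trailer)))
  scope <- if (tok %in% SYNONYM_SCOPES) tok else "RELATED"
  synonym(text, scope)
}

#' Write an ontology as OBO flat-file text
#'
#' Emits a minimal header (`format-version`, `ontology`) followed by one
#' `[Term]` stanza per term in ascending id order. The output re-parses to an
#' ontology equal to the input field-for-field.
#'
#' @param x An [ontology()].
#' @param file Path or connection; if `NULL` the text is returned only.
#' @return The OBO text, invisibly when written to `file`.
#' @export
write_obo <- function(x, file = NULL) {
  stopifnot(inherits(x, "ontology"))
  out <- c("format-version: 1.2",
           paste0("ontology: ", tolower(x$prefix)))
  for (t in x$terms) {  # constructor guarantees ascending id order
    stanza <- c("", "[Term]", paste0("id: ", t$id), paste0("name: ", t$label))
    for (s in t$synonyms) {
      esc <- gsub('(["\\\\])', "\\\\\\1", s$text)
      stanza <- c(stanza, sprintf('synonym: "%s" %s []', esc, s$scope))
    }
    stanza <- c(stanza, paste0("xref: ", t$xrefs))
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza)
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
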