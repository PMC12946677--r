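#' Tokenize a term label
#'
#' Splits on every maximal run of non-alphanumeric characters (spaces and
#' all punctuation are separators), lowercases each token and drops empty
#' tokens, preserving original order. Diacritics are not stripped.
#'
#' @param label A single string (possibly empty).
#' @return Character vector of tokens; `character(0)` for empty input.
#' @export
#' @examples
#' tokenize("Type 2 diabetes mellitus")
#' tokenize("blood pressure, systolic")
tokenize <- function(label) {
  if (length(label) == 0L || is.na(label)) return(character())
  toks <- strsplit(tolower(as.character(label)[1L]), "[^[:alnum:]]+")[[1L]]
  toks[nzchar(toks)]
}

#' Build the normalized search keyword for a label
#'
#' Tokens from [tokenize()] are sorted in code-point (C-locale) order — so
#' digit tokens sort before letters — and concatenated with no separator.
#' Labels that are word permutations of each other, or differ only in case
#' or punctuation, yield identical keywords.
#'
#' @param label Character vector of labels (vectorized).
#' @return Character vector of keywords; an empty label yields `""`, which
#'   is never indexed.
#' @export
#' @examples
#' make_keyword("Type 2 diabetes mellitus")     # "2diabetesmellitustype"
#' make_keyword("Blood pressure, systolic") ==
#'   make_keyword("systolic blood pressure")
make_keyword <- function(label) {
  vapply(as.character(label), function(l) {
    paste(sort(tokenize(l), method = "radix"), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Keywords of a term (label plus all synonyms)
#'
#' The deduplicated set of keywords from the term's label and every synonym
#' text, regardless of synonym scope. Empty keywords are excluded.
#'
#' @param term An [ontology_term()].
#' @return Character vector of distinct keywords.
#' @export
term_keywords <- function(term) {
  stopifnot(inherits(term, "onto_term"))
  texts <- c(term$label, vapply(term$synonyms, `[[`, "", "text"))
  kw <- unique(make_keyword(texts))
  kw[nzchar(kw)]
}
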