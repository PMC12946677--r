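#' Normalize a CURIE or OBO-style URI to canonical form
#'
#' Canonical form is `PREFIX:local` with the prefix upper-cased and all
#' internal whitespace removed. OBO-style URIs (anything containing `/` or
#' `#`) are reduced to their tail, where the first underscore separates
#' prefix from local id: `http://www.ebi.ac.uk/efo/EFO_0000400` becomes
#' `EFO:0000400`. Prefix synonymy such as MeSH/MESH is resolved by the
#' case-insensitive comparison only; no external prefix registry is
#' consulted. The function is idempotent.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of canonical CURIEs.
#' @export
#' @examples
#' normalize_curie(c("MeSH:D006973", "http://www.ebi.ac.uk/efo/EFO_0000400"))
normalize_curie <- function(x) {
  vapply(as.character(x), function(raw) {
    if (is.na(raw)) stop("cannot parse CURIE from: NA", call. = FALSE)
    v <- gsub("[[:space:]]+", "", raw)
    if (grepl("[/#]", v)) v <- sub(".*[/#]", "", v)
    if (grepl(":", v, fixed = TRUE)) {
      prefix <- sub(":.*$", "", v)
      local <- sub("^[^:]*:", "", v)
    } else if (grepl("_", v, fixed = TRUE)) {
      prefix <- sub("_.*$", "", v)
      local <- sub("^[^_]*_", "", v)
    } else {
      stop("cannot parse CURIE from: ", raw, call. = FALSE)
    }
    if (!nzchar(prefix) || !nzchar(local)) {
      stop("cannot parse CURIE from: ", raw, call. = FALSE)
    }
    paste0(toupper(prefix), ":", local)
  }, "", USE.NAMES = FALSE)
}

#' Extract the prefix of a canonical CURIE
#' @param x Character vector of CURIEs.
#' @return Character vector of prefixes.
#' @export
curie_prefix <- function(x) sub(":.*$", "", x)
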