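#' Parse a GWAS-catalog-style association table
#'
#' Reads a TSV with one SNP-trait association per row. Required columns
#' (matched case-insensitively): a SNP id column (`SNPS`), a trait label
#' column (`DISEASE/TRAIT`) and a mapped-trait URI column
#' (`MAPPED_TRAIT_URI`); optional background-trait URI (any column whose
#' name contains `BACKGROUND` and `URI`) and p-value (`P-VALUE`) columns.
#' Multiple URIs in one cell may be separated by `|` or `, `. Every URI is
#' normalized to a CURIE via [normalize_curie()]; rows with no parseable
#' trait URI are skipped with a warning and counted in the `n_skipped`
#' attribute. When the input has no QTL name column, names are minted as
#' `GWAS<row>_H`.
#'
#' @param file Path to the TSV (or a connection).
#' @param text Alternatively the TSV text itself.
#' @return Data frame with columns `snp_id`, `qtl_name`, `trait_label`,
#'   `p_value` and list-columns `trait_ids`, `background_trait_ids`.
#' @export
parse_gwas_associations <- function(file = NULL, text = NULL) {
  df <- if (is.null(text)) {
    utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", quote = "")
  } else {
    utils::read.delim(text = text, stringsAsFactors = FALSE,
                      check.names = FALSE, colClasses = "character",
                      quote = "")
  }
  nm <- toupper(names(df))
  find_col <- function(pattern) {
    i <- grep(pattern, nm)
    if (length(i)) names(df)[i[1L]] else NA_character_
  }
  snp_col <- find_col("^SNPS?$|^SNP_ID$")
  trait_col <- find_col("^DISEASE[ /.]?TRAIT$|^TRAIT$")
  uri_col <- find_col("^MAPPED_TRAIT_URI$")
  required <- c(SNPS = snp_col, `DISEASE/TRAIT` = trait_col,
                MAPPED_TRAIT_URI = uri_col)
  if (anyNA(required)) {
    stop("association table missing required column(s): ",
         paste(names(required)[is.na(required)], collapse = ", "),
         call. = FALSE)
  }
  bg_col <- find_col("BACKGROUND.*URI")
  p_col <- find_col("^P.?VALUE$")
  qtl_col <- find_col("^QTL")

  split_uris <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character())
    parts <- strsplit(cell, "\\s*\\|\\s*|,\\s+")[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    out <- character()
    for (p in parts) {
      v <- tryCatch(normalize_curie(p), error = function(e) NA_character_)
      if (!is.na(v)) out <- c(out, v)
    }
    unique(out)
  }

  n <- nrow(df)
  trait_ids <- lapply(df[[uri_col]], split_uris)
  bg_ids <- if (!is.na(bg_col)) lapply(df[[bg_col]], split_uris) else
    replicate(n, character(), simplify = FALSE)
  keep <- lengths(trait_ids) > 0L
  n_skipped <- sum(!keep)
  if (n_skipped) {
    warning(n_skipped, " row(s) without a parseable mapped-trait URI skipped",
            call. = FALSE)
  }
  qtl <- if (!is.na(qtl_col)) df[[qtl_col]] else sprintf("GWAS%d_H", seq_len(n))
  out <- data.frame(
    snp_id = df[[snp_col]][keep],
    qtl_name = qtl[keep],
    trait_label = df[[trait_col]][keep],
    p_value = if (!is.na(p_col)) df[[p_col]][keep] else rep("", sum(keep)),
    stringsAsFactors = FALSE)
  out$trait_ids <- trait_ids[keep]
  out$background_trait_ids <- bg_ids[keep]
  attr(out, "n_skipped") <- n_skipped
  out
}

## long (qtl_name, trait_id, background) view of an association table
association_traits <- function(associations) {
  n_fg <- lengths(associations$trait_ids)
  n_bg <- lengths(associations$background_trait_ids)
  data.frame(
    qtl_name = c(rep(associations$qtl_name, n_fg),
                 rep(associations$qtl_name, n_bg)),
    trait_id = c(unlist(associations$trait_ids, use.names = FALSE),
                 unlist(associations$background_trait_ids, use.names = FALSE)),
    background = c(rep(FALSE, sum(n_fg)), rep(TRUE, sum(n_bg))),
    stringsAsFactors = FALSE)
}

#' Translate EFO trait annotations into a mapped target ontology
#'
#' For every association, every trait id (and every background trait id,
#' flagged `background = TRUE`) and every ACCEPTED mapping whose subject is
#' that trait, whose object carries the requested target prefix, and whose
#' predicate is allowed, one annotation is emitted on the QTL-like record.
#' The default predicate set is `skos:exactMatch` only — the conservative
#' choice; broader propagation is enabled by passing more predicates.
#' Output is deduplicated on (qtl_name, term_id, source_term_id) and sorted
#' deterministically.
#'
#' @param associations Result of [parse_gwas_associations()].
#' @param mappings A [mapping_set()]; only ACCEPTED records are used.
#' @param target_prefix CURIE prefix of the target ontology (e.g. `"DOID"`).
#' @param allowed_predicates Predicates eligible for propagation.
#' @return Data frame with columns `qtl_name`, `term_id`, `term_label`,
#'   `source_term_id`, `mapping_predicate`, `background`.
#' @export
translate_annotations <- function(associations, mappings, target_prefix,
                                  allowed_predicates = "skos:exactMatch") {
  stopifnot(inherits(mappings, "mapping_set"))
  acc <- accepted_records(mappings)
  acc <- acc[curie_prefix(acc$object_id) == toupper(target_prefix) &
             acc$predicate %in% allowed_predicates, , drop = FALSE]
  traits <- association_traits(associations)
  empty <- data.frame(qtl_name = character(), term_id = character(),
                      term_label = character(), source_term_id = character(),
                      mapping_predicate = character(), background = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(traits) || !nrow(acc)) return(empty)
  hit <- merge(traits, acc, by.x = "trait_id", by.y = "subject_id")
  if (!nrow(hit)) return(empty)
  out <- data.frame(
    qtl_name = hit$qtl_name, term_id = hit$object_id,
    term_label = hit$object_label, source_term_id = hit$trait_id,
    mapping_predicate = hit$predicate, background = hit$background,
    stringsAsFactors = FALSE)
  ## foreground wins when the same triple occurs both ways
  out <- out[order(out$qtl_name, out$term_id, out$source_term_id,
                   out$background, method = "radix"), , drop = FALSE]
  out <- out[!duplicated(out[c("qtl_name", "term_id", "source_term_id")]), ,
             drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Detect trait terms with no accepted mapping
#'
#' The set of trait and background-trait CURIEs appearing in the
#' associations that have zero ACCEPTED mappings into any target prefix —
#' the log a curation team monitors for terms that still need mapping.
#'
#' @param associations Result of [parse_gwas_associations()].
#' @param mappings A [mapping_set()].
#' @return Sorted character vector of CURIEs.
#' @export
detect_unmapped_terms <- function(associations, mappings) {
  stopifnot(inherits(mappings, "mapping_set"))
  traits <- unique(association_traits(associations)$trait_id)
  mapped <- unique(accepted_records(mappings)$subject_id)
  sort(setdiff(traits, mapped), method = "radix")
}

#' Write translated annotations as TSV
#' @param annotations Result of [translate_annotations()].
#' @param file Path or connection.
#' @return `annotations`, invisibly.
#' @export
write_annotations <- function(annotations, file) {
  utils::write.table(annotations, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(annotations)
}
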