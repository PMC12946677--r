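#' Per-target-ontology mapping statistics
#'
#' Counts, for each target ontology prefix, the distinct subject terms with
#' at least one ACCEPTED mapping into that prefix, split by provenance: a
#' subject is counted as `automated` when any of its accepted mappings into
#' the prefix carries justification `LEXICAL_AUTOMATED` (automation found
#' it, curators confirmed it) and as `manual` otherwise. A subject mapped to
#' several targets within one prefix counts once. `pct_automated` is the
#' integer percentage, rounded half-up.
#'
#' @param set A [mapping_set()].
#' @return Data frame with one row per prefix (sorted): `prefix`,
#'   `total_mapped`, `automated`, `manual`, `pct_automated`.
#' @export
mapping_stats <- function(set) {
  stopifnot(inherits(set, "mapping_set"))
  acc <- accepted_records(set)
  empty <- data.frame(prefix = character(), total_mapped = integer(),
                      automated = integer(), manual = integer(),
                      pct_automated = integer(), stringsAsFactors = FALSE)
  if (!nrow(acc)) return(empty)
  acc$prefix <- curie_prefix(acc$object_id)
  parts <- lapply(split(acc, acc$prefix), function(g) {
    subjects <- unique(g$subject_id)
    auto <- unique(g$subject_id[g$justification == "LEXICAL_AUTOMATED"])
    n_total <- length(subjects)
    n_auto <- length(auto)
    data.frame(prefix = g$prefix[1L], total_mapped = n_total,
               automated = n_auto, manual = n_total - n_auto,
               pct_automated = as.integer(floor(100 * n_auto / n_total + 0.5)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$prefix, method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Render mapping statistics as TSV text
#' @param stats Result of [mapping_stats()].
#' @param file Optional path or connection.
#' @return The TSV text, invisibly when written to `file`.
#' @export
render_stats_table <- function(stats, file = NULL) {
  lines <- c(paste(c("prefix", "total_mapped", "automated", "manual",
                     "pct_automated"), collapse = "\t"),
             if (nrow(stats)) {
               paste(stats$prefix, stats$total_mapped, stats$automated,
                     stats$manual, stats$pct_automated, sep = "\t")
             })
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(lines, file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
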