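#' Propose mappings from database cross-reference identity
#'
#' A candidate is emitted with method `XREF` when (a) a source xref equals a
#' target term's id, (b) a target term's xref equals the source id, or (c)
#' source and target share any normalized third-party xref. Evidence lists
#' the mediating CURIE(s); tally is their count. All xref prefixes are
#' eligible mediators; prefix synonymy (MeSH/MESH) is resolved by the
#' case-insensitive canonicalization of [normalize_curie()] only.
#' Un-normalizable xrefs are skipped with a warning.
#'
#' @param source A non-obsolete [ontology_term()].
#' @param target An [ontology()].
#' @return Data frame with columns `source_id`, `target_id`, `tally`,
#'   `method` (always `"XREF"`), `evidence` (pipe-delimited mediating
#'   CURIEs), ranked by tally descending then target id.
#' @export
xref_candidates <- function(source, target) {
  stopifnot(inherits(source, "onto_term"), inherits(target, "ontology"))
  if (source$obsolete) {
    stop("obsolete terms do not participate in matching: ", source$id,
         call. = FALSE)
  }
  sx <- safe_normalize_xrefs(source$xrefs, source$id)
  sid <- source$id
  ids <- character(); tallies <- integer(); evid <- character()
  for (tid in active_term_ids(target)) {
    t <- target$terms[[tid]]
    med <- unique(c(
      intersect(sx, tid),        # (a) source xref hits target id
      intersect(t$xrefs, sid),   # (b) target xref hits source id
      intersect(sx, t$xrefs)     # (c) shared third-party xref
    ))
    if (length(med)) {
      ids <- c(ids, tid)
      tallies <- c(tallies, length(med))
      evid <- c(evid, paste(sort(med, method = "radix"), collapse = "|"))
    }
  }
  if (!length(ids)) return(empty_candidates())
  ord <- order(-tallies, ids, method = "radix")
  data.frame(source_id = sid, target_id = ids[ord], tally = tallies[ord],
             method = "XREF", evidence = evid[ord], row.names = NULL,
             stringsAsFactors = FALSE)
}

## term constructors already normalize xrefs; this guards hand-built input
safe_normalize_xrefs <- function(xrefs, owner) {
  out <- character()
  for (x in xrefs) {
    v <- tryCatch(normalize_curie(x), error = function(e) NA_character_)
    if (is.na(v)) {
      warning("skipping un-normalizable xref '", x, "' on term ", owner,
              call. = FALSE)
    } else {
      out <- c(out, v)
    }
  }
  unique(out)
}

#' XREF-match every source term against a target ontology
#'
#' Runs [xref_candidates()] for each non-obsolete source term in ascending
#' id order. A pair matched by both lexical and xref methods appears once
#' per method in a combined table, never merged silently.
#'
#' @param source,target [ontology()] objects.
#' @return Candidate data frame in the same shape as [match_ontology()],
#'   with `method == "XREF"`.
#' @export
xref_match_ontology <- function(source, target) {
  stopifnot(inherits(source, "ontology"), inherits(target, "ontology"))
  parts <- lapply(active_term_ids(source), function(id) {
    xref_candidates(source$terms[[id]], target)
  })
  decorate_candidates(do.call(rbind, c(parts, list(empty_candidates()))),
                      source, target)
}
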