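## biomedical-flavored word bank used to assemble fixture labels
FIXTURE_WORDS <- c(
  "systolic", "diastolic", "blood", "pressure", "diabetes", "mellitus",
  "type", "insulin", "glucose", "serum", "cholesterol", "triglyceride",
  "body", "mass", "index", "heart", "myocardial", "infarction", "cardiac",
  "failure", "hypertension", "artery", "coronary", "disease", "stroke",
  "asthma", "lung", "function", "forced", "expiratory", "volume", "bone",
  "mineral", "density", "arthritis", "rheumatoid", "kidney", "renal",
  "creatinine", "urate", "thyroid", "hormone", "platelet", "count",
  "erythrocyte", "leukocyte", "hemoglobin", "glycated", "waist",
  "circumference", "height", "weight", "obesity", "carcinoma", "breast",
  "prostate", "melanoma", "fasting", "response", "trait")

## evaluate code under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic ontology-pair fixture
#'
#' Counts of planted source/target term pairs per match class: identical
#' labels, word-permuted labels, punctuation/case variants, pairs that match
#' only through a synonym, pairs that share only a third-party xref, plus
#' unmatched distractor terms on either side. Distractor labels are built
#' from a token namespace disjoint from the word bank, so no distractor
#' keyword can collide with a planted keyword.
#'
#' @param n_exact_label,n_permuted,n_punct,n_synonym_only,n_xref_only
#'   Planted pair counts (each >= 0).
#' @param n_distractor_source,n_distractor_target Unmatched term counts.
#' @param seed Random seed controlling label/word selection.
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(n_exact_label = 0, n_permuted = 0, n_punct = 0,
                         n_synonym_only = 0, n_xref_only = 0,
                         n_distractor_source = 0, n_distractor_target = 0,
                         seed = 1L) {
  spec <- list(n_exact_label = n_exact_label, n_permuted = n_permuted,
               n_punct = n_punct, n_synonym_only = n_synonym_only,
               n_xref_only = n_xref_only,
               n_distractor_source = n_distractor_source,
               n_distractor_target = n_distractor_target,
               seed = as.integer(seed))
  counts <- unlist(spec[1:7])
  if (any(counts < 0)) stop("fixture counts must be >= 0", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

#' Generate a source/target ontology pair with planted ground truth
#'
#' Builds two toy ontologies emulating the structure a lexical/xref mapping
#' pipeline faces: a source (EFO-like) and a target, with pairs planted per
#' the [fixture_spec()] classes. Every planted pair is recorded in a truth
#' table with the method expected to discover it (`LEXICAL` for the four
#' label/synonym classes, `XREF` for xref-only pairs). Planted labels are
#' mutually distinct at the keyword level, so the matchers recover exactly
#' the truth set. Generation is deterministic given the spec seed.
#'
#' @param spec A [fixture_spec()].
#' @param source_prefix,target_prefix CURIE prefixes for the two sides.
#' @return List with elements `source`, `target` (ontologies) and `truth`
#'   (data frame `source_id`, `target_id`, `method`).
#' @export
gen_ontology_pair <- function(spec, source_prefix = "EFO",
                              target_prefix = "DOID") {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    used_kw <- character()
    draw_label <- function(n_words = 3L) {
      repeat {
        words <- sample(FIXTURE_WORDS, n_words)
        lab <- paste(words, collapse = " ")
        kw <- make_keyword(lab)
        if (!kw %in% used_kw) {
          used_kw <<- c(used_kw, kw)
          return(lab)
        }
      }
    }
    src <- list(); tgt <- list(); truth <- list()
    s_i <- 0L; t_i <- 0L
    next_src_id <- function() {
      s_i <<- s_i + 1L
      sprintf("%s:%07d", source_prefix, s_i)
    }
    next_tgt_id <- function() {
      t_i <<- t_i + 1L
      sprintf("%s:%07d", target_prefix, t_i)
    }
    plant <- function(src_term, tgt_term, method) {
      src[[length(src) + 1L]] <<- src_term
      tgt[[length(tgt) + 1L]] <<- tgt_term
      truth[[length(truth) + 1L]] <<- data.frame(
        source_id = src_term$id, target_id = tgt_term$id, method = method,
        stringsAsFactors = FALSE)
    }

    for (i in seq_len(spec$n_exact_label)) {
      lab <- draw_label()
      plant(ontology_term(next_src_id(), lab),
            ontology_term(next_tgt_id(), lab), "LEXICAL")
    }
    for (i in seq_len(spec$n_permuted)) {
      lab <- draw_label()
      words <- strsplit(lab, " ", fixed = TRUE)[[1L]]
      plant(ontology_term(next_src_id(), lab),
            ontology_term(next_tgt_id(), paste(rev(words), collapse = " ")),
            "LEXICAL")
    }
    for (i in seq_len(spec$n_punct)) {
      lab <- draw_label()
      words <- strsplit(lab, " ", fixed = TRUE)[[1L]]
      capped <- paste0(toupper(substr(words, 1, 1)), substring(words, 2))
      variant <- paste0(capped[1L], "-", paste(capped[-1L], collapse = ", "))
      plant(ontology_term(next_src_id(), lab),
            ontology_term(next_tgt_id(), variant), "LEXICAL")
    }
    for (i in seq_len(spec$n_synonym_only)) {
      lab_src <- draw_label()
      lab_tgt <- draw_label()
      plant(ontology_term(next_src_id(), lab_src,
                          synonyms = list(synonym(lab_tgt, "RELATED"))),
            ontology_term(next_tgt_id(), lab_tgt), "LEXICAL")
    }
    for (i in seq_len(spec$n_xref_only)) {
      xref <- sprintf("MESH:D%06d", i)
      plant(ontology_term(next_src_id(), draw_label(), xrefs = xref),
            ontology_term(next_tgt_id(), draw_label(), xrefs = xref), "XREF")
    }
    for (i in seq_len(spec$n_distractor_source)) {
      src[[length(src) + 1L]] <- ontology_term(
        next_src_id(), sprintf("srcfiller notion %03d", i))
    }
    for (i in seq_len(spec$n_distractor_target)) {
      tgt[[length(tgt) + 1L]] <- ontology_term(
        next_tgt_id(), sprintf("tgtfiller notion %03d", i))
    }

    truth <- do.call(rbind, c(truth, list(data.frame(
      source_id = character(), target_id = character(), method = character(),
      stringsAsFactors = FALSE))))
    truth <- truth[order(truth$source_id, truth$target_id, method = "radix"), ,
                   drop = FALSE]
    row.names(truth) <- NULL
    list(source = ontology(src, prefix = source_prefix),
         target = ontology(tgt, prefix = target_prefix),
         truth = truth)
  })
}

#' Generate a GWAS-catalog-style association TSV
#'
#' Mints `n_assoc` rows with rs-style SNP ids and mapped-trait URIs drawn
#' from the source ontology's non-obsolete terms. A deterministic fraction
#' of rows (`round(frac_unmapped * n_assoc)`, half-up, placed last) uses
#' URIs for fabricated term ids absent from the source ontology (and hence
#' from any mapping derived from it); `round(frac_background * n_assoc)`
#' rows (placed first) additionally carry a background-trait URI.
#'
#' @param source An [ontology()] with at least one non-obsolete term when
#'   `n_assoc > 0`.
#' @param n_assoc Number of association rows.
#' @param frac_unmapped Fraction of rows with a deliberately unmapped trait.
#' @param frac_background Fraction of rows carrying a background trait.
#' @param seed Random seed.
#' @param file Optional path to write the TSV to.
#' @return The TSV text (invisibly when written to `file`), with attribute
#'   `unmapped_ids` listing the planted unmapped CURIEs.
#' @export
gen_associations <- function(source, n_assoc, frac_unmapped = 0,
                             frac_background = 0, seed = 1L, file = NULL) {
  stopifnot(inherits(source, "ontology"))
  ids <- active_term_ids(source)
  if (n_assoc > 0 && !length(ids)) {
    stop("cannot generate associations from an ontology with no active terms",
         call. = FALSE)
  }
  header <- paste(c("SNPS", "DISEASE/TRAIT", "MAPPED_TRAIT_URI",
                    "MAPPED_BACKGROUND_TRAIT_URI", "P-VALUE"),
                  collapse = "\t")
  uri_of <- function(id) {
    paste0("http://www.ebi.ac.uk/efo/", sub(":", "_", id, fixed = TRUE))
  }
  txt <- with_seed(seed, {
    n_unmapped <- as.integer(floor(frac_unmapped * n_assoc + 0.5))
    n_bg <- as.integer(floor(frac_background * n_assoc + 0.5))
    unmapped_ids <- if (n_unmapped) {
      sprintf("%s:%07d", source$prefix, 9900000L + seq_len(n_unmapped))
    } else {
      character()
    }
    rows <- character(n_assoc)
    for (r in seq_len(n_assoc)) {
      snp <- sprintf("rs%d", sample.int(99999999L, 1L))
      unmapped_row <- r > n_assoc - n_unmapped
      if (unmapped_row) {
        tid <- unmapped_ids[r - (n_assoc - n_unmapped)]
        label <- "unmapped trait"
      } else {
        tid <- sample(ids, 1L)
        label <- term_label(source, tid)
      }
      bg <- if (r <= n_bg) uri_of(sample(ids, 1L)) else ""
      pval <- sprintf("%.1E", 10^(-stats::runif(1L, 6, 40)))
      rows[r] <- paste(snp, label, uri_of(tid), bg, pval, sep = "\t")
    }
    out <- paste0(paste(c(header, rows), collapse = "\n"), "\n")
    attr(out, "unmapped_ids") <- unmapped_ids
    out
  })
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}
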